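# Domain types: planning units, features, occurrences, boundary segments.
#
# A problem is a plain list of data frames plus a mode flag; an environment
# of precomputed lookup tables (row indices, per-occurrence loss
# probabilities, adjacency lists) rides along so that repeated objective
# evaluations do not pay for joins.

.PR_MODES <- c("deterministic", "threat_1d", "species_2d")

# status codes follow the classic encoding:
# 0 available, 1 available-initially-selected, 2 locked in, 3 locked out
.PR_STATUS <- 0:3

.pr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Assemble a reserve-selection problem
#'
#' Builds a validated problem instance from its component tables.  Rows may
#' arrive in any order; they are sorted internally (units and features by id,
#' occurrences by unit then feature) so that two problems with the same
#' content compare identical.
#'
#' @param pu data frame of planning units with columns `id` (positive
#'   integer), `cost` (non-negative), `status` (0 available, 1 available and
#'   initially selected, 2 locked in, 3 locked out) and optionally `prob`,
#'   the probability the whole site is lost over the planning horizon
#'   (threat mode).
#' @param features data frame with columns `id`, `target` (amount of the
#'   feature required in the reserve system), `spf` (feature penalty
#'   factor), and optionally `ptarget` (required probability of meeting the
#'   target; 0 disables the probability constraint) and `name`.
#' @param occ data frame of feature-by-unit occurrence amounts with columns
#'   `species`, `pu`, `amount` and optionally `prob`, the probability the
#'   occurrence actually exists (species mode).
#' @param bound optional data frame of boundary segments with columns `id1`,
#'   `id2`, `boundary`; a row with `id1 == id2` is the exposed (outer) edge
#'   of that unit.
#' @param mode one of `"deterministic"`, `"threat_1d"` (per-site loss
#'   probabilities) or `"species_2d"` (per-occurrence existence
#'   probabilities).
#' @param check validate the assembled problem and fail on any violation.
#' @return an object of class `pr_problem`.
#' @seealso [validate()], [read_problem()], [random_problem()]
#' @export
new_problem <- function(pu, features, occ, bound = NULL,
                        mode = c("deterministic", "threat_1d", "species_2d"),
                        check = TRUE) {
  mode <- match.arg(mode)

  pu <- as.data.frame(pu)
  for (col in c("id", "cost", "status")) {
    if (!col %in% names(pu)) {
      .pr_stop("pr_format_error", "planning-unit table lacks column '%s'", col)
    }
  }
  if (is.null(pu$prob)) pu$prob <- 0
  pu <- pu[order(pu$id), c("id", "cost", "status", "prob"), drop = FALSE]
  rownames(pu) <- NULL

  features <- as.data.frame(features)
  for (col in c("id", "target", "spf")) {
    if (!col %in% names(features)) {
      .pr_stop("pr_format_error", "feature table lacks column '%s'", col)
    }
  }
  if (is.null(features$ptarget)) features$ptarget <- 0
  if (is.null(features$name)) features$name <- paste0("feature_", features$id)
  features <- features[order(features$id),
                       c("id", "name", "target", "spf", "ptarget"),
                       drop = FALSE]
  rownames(features) <- NULL

  occ <- as.data.frame(occ)
  for (col in c("species", "pu", "amount")) {
    if (!col %in% names(occ)) {
      .pr_stop("pr_format_error", "occurrence table lacks column '%s'", col)
    }
  }
  if (is.null(occ$prob)) occ$prob <- 1
  occ <- occ[order(occ$pu, occ$species),
             c("species", "pu", "amount", "prob"), drop = FALSE]
  rownames(occ) <- NULL

  if (is.null(bound) || nrow(as.data.frame(bound)) == 0) {
    bound <- data.frame(id1 = integer(), id2 = integer(), boundary = numeric())
  } else {
    bound <- as.data.frame(bound)
    for (col in c("id1", "id2", "boundary")) {
      if (!col %in% names(bound)) {
        .pr_stop("pr_format_error", "boundary table lacks column '%s'", col)
      }
    }
    a <- pmin(bound$id1, bound$id2)
    b <- pmax(bound$id1, bound$id2)
    bound <- data.frame(id1 = a, id2 = b, boundary = bound$boundary)
    bound <- bound[order(bound$id1, bound$id2), , drop = FALSE]
    rownames(bound) <- NULL
  }

  problem <- structure(
    list(pu = pu, features = features, occ = occ, bound = bound,
         mode = mode, index = NULL),
    class = "pr_problem"
  )
  if (check) {
    v <- validate(problem)
    if (nrow(v) > 0) {
      .pr_stop("pr_validation_error", "invalid problem:\n%s",
               paste(sprintf("- %s %s, %s: %s", v$entity, v$id, v$field, v$rule),
                     collapse = "\n"))
    }
  }
  problem$index <- .pr_build_index(problem)
  problem$features$repcost <-
    vapply(problem$features$id, function(fid) {
      .pr_repcost(problem, fid)
    }, numeric(1))
  problem
}

# Lookup tables shared by the objective and probability engines.  Stored in
# an environment so copies of the problem list share (and keep) them.
.pr_build_index <- function(problem) {
  idx <- new.env(parent = emptyenv())
  pu <- problem$pu
  occ <- problem$occ
  idx$n <- nrow(pu)
  idx$m <- nrow(problem$features)
  idx$occ_u <- match(occ$pu, pu$id)
  idx$occ_f <- match(occ$species, problem$features$id)
  idx$q <- switch(problem$mode,
    deterministic = rep(0, nrow(occ)),
    threat_1d = pu$prob[idx$occ_u],
    species_2d = 1 - occ$prob
  )
  idx$feat_rows <- split(seq_len(nrow(occ)), factor(idx$occ_f, levels = seq_len(idx$m)))
  idx$unit_rows <- split(seq_len(nrow(occ)), factor(idx$occ_u, levels = seq_len(idx$n)))

  b <- problem$bound
  ba <- match(b$id1, pu$id)
  bb <- match(b$id2, pu$id)
  self <- !is.na(ba) & !is.na(bb) & ba == bb
  idx$bnd_a <- ba
  idx$bnd_b <- bb
  idx$bnd_self <- self
  selfv <- numeric(idx$n)
  if (any(self)) {
    agg <- tapply(b$boundary[self], ba[self], sum)
    selfv[as.integer(names(agg))] <- as.numeric(agg)
  }
  idx$selfv <- selfv
  adj_nb <- vector("list", idx$n)
  adj_v <- vector("list", idx$n)
  for (i in seq_len(idx$n)) {
    adj_nb[[i]] <- integer()
    adj_v[[i]] <- numeric()
  }
  if (any(!self)) {
    ea <- ba[!self]; eb <- bb[!self]; ev <- b$boundary[!self]
    for (k in seq_along(ea)) {
      adj_nb[[ea[k]]] <- c(adj_nb[[ea[k]]], eb[k])
      adj_v[[ea[k]]] <- c(adj_v[[ea[k]]], ev[k])
      adj_nb[[eb[k]]] <- c(adj_nb[[eb[k]]], ea[k])
      adj_v[[eb[k]]] <- c(adj_v[[eb[k]]], ev[k])
    }
  }
  idx$adj_nb <- adj_nb
  idx$adj_v <- adj_v
  idx
}

#' Check a problem against its structural invariants
#'
#' Returns violations as data, not errors: unique positive ids, non-negative
#' costs and amounts, probabilities inside \[0, 1\], referential integrity of
#' the occurrence and boundary tables, and mode consistency (threat mode
#' forbids per-occurrence probabilities other than 1; species mode forbids
#' non-zero site loss probabilities).
#'
#' @param problem a `pr_problem`.
#' @return data frame with columns `entity`, `id`, `field`, `rule`; zero rows
#'   when the problem is well formed.
#' @export
validate <- function(problem) {
  stopifnot(inherits(problem, "pr_problem"))
  v <- list()
  bad <- function(entity, id, field, rule) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, id = as.character(id),
                                       field = field, rule = rule)
  }
  pu <- problem$pu; fe <- problem$features; oc <- problem$occ; bd <- problem$bound

  if (anyDuplicated(pu$id)) {
    for (d in unique(pu$id[duplicated(pu$id)])) bad("planning_unit", d, "id", "duplicate id")
  }
  for (i in which(!(pu$id > 0 & pu$id == round(pu$id)))) {
    bad("planning_unit", pu$id[i], "id", "id must be a positive integer")
  }
  for (i in which(pu$cost < 0)) bad("planning_unit", pu$id[i], "cost", "cost must be >= 0")
  for (i in which(!pu$status %in% .PR_STATUS)) {
    bad("planning_unit", pu$id[i], "status", "status must be one of 0,1,2,3")
  }
  for (i in which(pu$prob < 0 | pu$prob > 1)) {
    bad("planning_unit", pu$id[i], "prob", "loss probability must be in [0,1]")
  }

  if (anyDuplicated(fe$id)) {
    for (d in unique(fe$id[duplicated(fe$id)])) bad("feature", d, "id", "duplicate id")
  }
  for (i in which(!(fe$id > 0 & fe$id == round(fe$id)))) {
    bad("feature", fe$id[i], "id", "id must be a positive integer")
  }
  for (i in which(fe$target < 0)) bad("feature", fe$id[i], "target", "target must be >= 0")
  for (i in which(fe$spf < 0)) bad("feature", fe$id[i], "spf", "penalty factor must be >= 0")
  for (i in which(fe$ptarget < 0 | fe$ptarget > 1)) {
    bad("feature", fe$id[i], "ptarget", "probability target must be in [0,1]")
  }

  key <- paste(oc$species, oc$pu)
  if (anyDuplicated(key)) {
    for (d in unique(key[duplicated(key)])) {
      bad("occurrence", d, "(species,pu)", "duplicate (feature, unit) pair")
    }
  }
  for (i in which(!(oc$amount > 0))) {
    bad("occurrence", sprintf("row %d", i), "amount", "amount must be > 0")
  }
  for (i in which(oc$prob < 0 | oc$prob > 1)) {
    bad("occurrence", sprintf("row %d", i), "prob", "probability must be in [0,1]")
  }
  for (i in which(!oc$pu %in% pu$id)) {
    bad("occurrence", sprintf("row %d", i), "pu",
        sprintf("references unknown planning unit %s", oc$pu[i]))
  }
  for (i in which(!oc$species %in% fe$id)) {
    bad("occurrence", sprintf("row %d", i), "species",
        sprintf("references unknown feature %s", oc$species[i]))
  }

  if (nrow(bd) > 0) {
    bkey <- paste(pmin(bd$id1, bd$id2), pmax(bd$id1, bd$id2))
    if (anyDuplicated(bkey)) {
      for (d in unique(bkey[duplicated(bkey)])) {
        bad("boundary", d, "(id1,id2)", "duplicate segment")
      }
    }
    for (i in which(bd$boundary < 0)) {
      bad("boundary", sprintf("row %d", i), "boundary", "length must be >= 0")
    }
    for (i in which(!bd$id1 %in% pu$id)) {
      bad("boundary", sprintf("row %d", i), "id1",
          sprintf("references unknown planning unit %s", bd$id1[i]))
    }
    for (i in which(!bd$id2 %in% pu$id)) {
      bad("boundary", sprintf("row %d", i), "id2",
          sprintf("references unknown planning unit %s", bd$id2[i]))
    }
  }

  if (problem$mode == "threat_1d") {
    for (i in which(oc$prob != 1)) {
      bad("occurrence", sprintf("row %d", i), "prob",
          "threat mode forbids per-occurrence probabilities other than 1")
    }
  }
  if (problem$mode == "species_2d") {
    for (i in which(pu$prob != 0)) {
      bad("planning_unit", pu$id[i], "prob",
          "species mode forbids non-zero site loss probabilities")
    }
  }

  if (length(v) == 0) {
    data.frame(entity = character(), id = character(),
               field = character(), rule = character())
  } else {
    do.call(rbind, v)
  }
}

#' @export
print.pr_problem <- function(x, ...) {
  cat(sprintf("Reserve-selection problem: %d planning units, %d features, %d occurrences\n",
              nrow(x$pu), nrow(x$features), nrow(x$occ)))
  cat(sprintf("mode: %s; boundary segments: %d\n", x$mode, nrow(x$bound)))
  invisible(x)
}

.pr_feature_row <- function(problem, feature_id) {
  r <- match(feature_id, problem$features$id)
  if (is.na(r)) .pr_stop("pr_lookup_error", "unknown feature id %s", feature_id)
  r
}

.pr_unit_row <- function(problem, unit_id) {
  r <- match(unit_id, problem$pu$id)
  if (is.na(r)) .pr_stop("pr_lookup_error", "unknown planning unit id %s", unit_id)
  r
}

#' Build a selection vector from planning-unit ids
#'
#' @param problem a `pr_problem`.
#' @param ids planning-unit ids to select.
#' @return integer 0/1 vector aligned with `problem$pu` (rows sorted by id).
#' @export
solution_from_ids <- function(problem, ids) {
  x <- integer(nrow(problem$pu))
  if (length(ids)) x[vapply(ids, function(i) .pr_unit_row(problem, i), 1L)] <- 1L
  x
}

.pr_check_solution <- function(problem, solution) {
  if (length(solution) != nrow(problem$pu) || !all(solution %in% c(0L, 1L))) {
    .pr_stop("pr_contract_error",
             "solution must be a 0/1 vector of length %d", nrow(problem$pu))
  }
  as.integer(solution)
}
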