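# Classical rough-set machinery over a decision system S = (U, A, V, f):
# indiscernibility partitions, lower/upper approximations, positive and
# boundary regions, dependency degree gamma, attribute significance, active
# regions, and the local-redundancy stability-measure (LRSM) forward
# attribute reduction.
#
# Values are compared by EXACT equality (no binning happens in this
# module); continuous features intended for equivalence-class analysis
# should be quantised upstream.

#' Construct a decision system
#'
#' @param data data frame of conditional attribute columns (numeric or
#'   categorical), one row per object.  No missing values are allowed.
#' @param decision vector of decision labels, one per object.
#' @param ids optional object identifiers (default `u1, u2, ...`).
#' @return an object of class `decision_system` with fields `ids`,
#'   `attributes` (data frame), `attrs` (attribute names), `decision`
#'   (character vector).
#' @export
decision_system <- function(data, decision, ids = NULL) {
  data <- as.data.frame(data)
  if (anyNA(data) || anyNA(decision)) {
    stop("decision system must not contain missing values")
  }
  if (nrow(data) != length(decision)) {
    stop("decision length must equal the number of objects")
  }
  if (anyDuplicated(names(data))) stop("attribute names must be unique")
  if (is.null(ids)) ids <- paste0("u", seq_len(nrow(data)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("object ids must be unique")
  structure(list(ids = ids,
                 attributes = data,
                 attrs = names(data),
                 decision = as.character(decision)),
            class = "decision_system")
}

#' Restrict a decision system to a subset of objects
#' @param ds a [decision_system()].
#' @param ids object identifiers to keep.
#' @return the restricted decision system.
#' @export
ds_restrict <- function(ds, ids) {
  keep <- match(ids, ds$ids)
  if (anyNA(keep)) stop("unknown object id")
  decision_system(ds$attributes[keep, , drop = FALSE],
                  ds$decision[keep], ds$ids[keep])
}

# Exact-equality row keys over attribute set B ("" for B = empty: one block).
row_keys <- function(ds, B) {
  if (length(B) == 0) return(rep("", length(ds$ids)))
  cols <- lapply(ds$attributes[B], function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  do.call(paste, c(cols, sep = "\r"))
}

check_attrs <- function(ds, B) {
  bad <- setdiff(B, c(ds$attrs, "decision"))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
}

#' Indiscernibility partition
#'
#' Groups objects by exact equality of all values on `B` (the equivalence
#' classes of the indiscernibility relation).  `B = character(0)` yields
#' the single block `U`.
#'
#' @param ds a [decision_system()].
#' @param B character vector of attribute names (subset of the conditional
#'   attributes, optionally `"decision"`).
#' @return list of character vectors of object ids (blocks, in order of
#'   first appearance).
#' @export
ds_partition <- function(ds, B) {
  check_attrs(ds, B)
  keys <- if ("decision" %in% B) {
    paste(row_keys(ds, setdiff(B, "decision")), ds$decision, sep = "\r")
  } else row_keys(ds, B)
  unname(split(ds$ids, factor(keys, levels = unique(keys))))
}

#' Lower and upper approximations of an object set
#'
#' The lower approximation is the union of `B`-blocks contained in `X`
#' (objects certainly in `X`); the upper approximation the union of blocks
#' intersecting `X` (objects possibly in `X`).
#'
#' @param ds a [decision_system()].
#' @param B attribute names inducing the partition.
#' @param X character vector of object ids, a subset of the universe.
#' @return list with `lower` and `upper` id vectors.
#' @export
approximations <- function(ds, B, X) {
  if (length(setdiff(X, ds$ids))) stop("X must be a subset of the universe")
  blocks <- ds_partition(ds, B)
  lower <- unlist(blocks[vapply(blocks, function(b) all(b %in% X), TRUE)])
  upper <- unlist(blocks[vapply(blocks, function(b) any(b %in% X), TRUE)])
  list(lower = as.character(sort_ids(ds, lower)),
       upper = as.character(sort_ids(ds, upper)))
}

# report object sets in universe order
sort_ids <- function(ds, ids) ds$ids[sort(match(unique(ids), ds$ids))]

#' Positive region, boundary region, and dependency degree
#'
#' The positive region of the decision with respect to `B` is the union of
#' lower approximations of the decision classes; the boundary region is the
#' union of upper approximations minus the positive region; gamma is
#' `|positive| / |U|` (a larger positive region indicates stronger
#' dependency of the decision on `B`).
#'
#' @param ds a [decision_system()].
#' @param B conditional attribute names.
#' @return list with `positive`, `boundary`, `lower`, `upper` (per-class
#'   lists) and `gamma`.
#' @export
positive_region <- function(ds, B) {
  check_attrs(ds, B)
  blocks <- ds_partition(ds, B)
  dec <- stats::setNames(ds$decision, ds$ids)
  pure <- vapply(blocks, function(b) length(unique(dec[b])) == 1L, TRUE)
  positive <- unlist(blocks[pure])
  if (is.null(positive)) positive <- character(0)
  classes <- unique(ds$decision)
  uppers <- lapply(classes, function(cl) {
    unlist(blocks[vapply(blocks, function(b) any(dec[b] == cl), TRUE)])
  })
  boundary <- setdiff(unique(unlist(uppers)), positive)
  list(positive = sort_ids(ds, positive),
       boundary = sort_ids(ds, boundary),
       gamma = length(positive) / length(ds$ids))
}

#' Dependency degree gamma
#' @inheritParams positive_region
#' @return `|POS_B(D)| / |U|`.
#' @export
gamma_dependency <- function(ds, B) positive_region(ds, B)$gamma

#' Attribute significance by dependency drop
#'
#' `sig(a, B) = gamma(B) - gamma(B \ {a})`: how much dependency is lost
#' when `a` is removed from `B`.
#'
#' @param ds a [decision_system()].
#' @param a attribute name, must belong to `B`.
#' @param B conditional attribute names.
#' @return non-negative real (by monotonicity of the positive region).
#' @export
sig_gamma <- function(ds, a, B) {
  if (!(a %in% B)) stop("attribute ", a, " is not in B")
  gamma_dependency(ds, B) - gamma_dependency(ds, setdiff(B, a))
}

#' Active / non-active region of an attribute
#'
#' The non-active region of `a` with respect to `B` is the union of blocks
#' of the `B`-partition that survive unchanged as blocks of the
#' `B + a`-partition; the active region is its complement -- the objects
#' whose equivalence classes are actually refined by `a`.  Only the active
#' region matters when assessing whether `a` is non-redundant.
#'
#' @param ds a [decision_system()].
#' @param B conditional attribute names not containing `a`.
#' @param a attribute name to assess.
#' @return list with `non_active` and `active` id vectors (a disjoint cover
#'   of the universe).
#' @export
active_region <- function(ds, B, a) {
  if (a %in% B) stop("attribute ", a, " must not belong to B")
  check_attrs(ds, c(B, a))
  before <- ds_partition(ds, B)
  after <- ds_partition(ds, c(B, a))
  after_keys <- vapply(after, function(b) paste(sort(b), collapse = ","), "")
  surviving <- vapply(before, function(b) {
    paste(sort(b), collapse = ",") %in% after_keys
  }, TRUE)
  non_active <- unlist(before[surviving])
  if (is.null(non_active)) non_active <- character(0)
  list(non_active = sort_ids(ds, non_active),
       active = sort_ids(ds, setdiff(ds$ids, non_active)))
}

#' Relative significance (RSIG)
#'
#' The relative significance of `a` within `B` balances the gain in
#' positive-region points against the growth in equivalence classes:
#' \deqn{RSIG(a, B, D) = \frac{|POS_B(D)| - |POS_{B-a}(D)|}
#'                            {|U/B| - |U/(B-a)|}}
#' A large positive-region gain achieved only through many extra
#' equivalence classes (an overfitting-prone split) is down-weighted.  When
#' removing `a` changes neither the partition cardinality (denominator 0,
#' e.g. a duplicated attribute) the attribute adds no discernibility and
#' RSIG is 0 by convention.
#'
#' @param ds a [decision_system()].
#' @param a attribute name, must belong to `B`.
#' @param B conditional attribute names.
#' @return the RSIG ratio (0 on a zero denominator).
#' @export
rsig <- function(ds, a, B) {
  if (!(a %in% B)) stop("attribute ", a, " is not in B")
  check_attrs(ds, B)
  Bm <- setdiff(B, a)
  d_pos <- length(positive_region(ds, B)$positive) -
           length(positive_region(ds, Bm)$positive)
  d_cls <- length(ds_partition(ds, B)) - length(ds_partition(ds, Bm))
  if (d_cls == 0) 0 else d_pos / d_cls
}

#' LRSM attribute reduction
#'
#' Greedy forward selection with local-redundancy pruning:
#' \enumerate{
#'   \item start with the full candidate pool and an empty reduct, working
#'     universe = all objects that are decidable at all, i.e. the positive
#'     region of the FULL attribute set (objects outside it can never enter
#'     any positive region, by monotonicity, and are irrelevant to further
#'     computations);
#'   \item drop candidates with zero significance on the working universe;
#'   \item pick the candidate with maximal RSIG (relative to pool + reduct;
#'     ties broken toward the earliest declared attribute);
#'   \item if its relative importance is positive, move it into the reduct
#'     and shrink the working universe by the positive region already
#'     decided by the reduct;
#'   \item repeat while candidates and undecided objects remain.
#' }
#' On a consistent decision system this is the standard dependency-
#' preserving greedy (the returned reduct satisfies
#' `gamma(reduct) == gamma(C)`).  On inconsistent systems redundancy is
#' judged locally on the decidable objects, which can retire attributes
#' whose only contribution is to separate undecidable objects.
#'
#' @param ds a [decision_system()] with a non-empty attribute set.
#' @return character vector of selected attribute names (in selection
#'   order).
#' @export
lrsm_reduce <- function(ds) {
  if (length(ds$attrs) == 0) stop("decision system has no conditional attributes")
  pool <- ds$attrs
  reduct <- character(0)
  decidable <- positive_region(ds, ds$attrs)$positive
  working <- decidable
  while (length(pool) > 0 && length(working) > 0) {
    sub <- ds_restrict(ds, working)
    # Theorem-3 pruning: retire zero-significance candidates one at a time
    # (later-declared attributes first, so mutually redundant candidates
    # resolve toward the earliest declaration), recomputing after each
    # removal -- dropping two attributes that are only redundant given each
    # other would lose dependency.
    repeat {
      if (length(pool) == 0) break
      sig <- vapply(pool, function(a) {
        sig_gamma(sub, a, unique(c(reduct, pool)))
      }, numeric(1))
      zero <- which(sig <= 0)
      if (length(zero) == 0) break
      pool <- pool[-zero[length(zero)]]
    }
    if (length(pool) == 0) break
    rs <- vapply(pool, function(a) rsig(sub, a, unique(c(reduct, pool))), numeric(1))
    best <- pool[which.max(rs)]      # which.max: lowest-index tie-break
    if (rs[which.max(rs)] <= 0) break
    reduct <- c(reduct, best)
    pool <- setdiff(pool, best)
    pos_now <- positive_region(sub, reduct)$positive
    working <- setdiff(working, pos_now)
  }
  if (length(reduct) == 0) reduct <- ds$attrs[1]
  reduct
}
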