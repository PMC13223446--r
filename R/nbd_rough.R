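# Neighborhood rough sets: delta-neighborhoods under a metric on the
# attribute space, neighborhood approximations, conditional information
# entropy (CIE), attribute importance, and the entropy-driven greedy
# reduction (NBD-RS).  Neighborhoods generalise indiscernibility to
# continuous data: at delta = 0 with all-distinct rows everything reduces
# to the classical operators.

#' Construct a neighborhood decision system
#'
#' @param ds a [decision_system()].
#' @param delta neighborhood radius, `>= 0`, in (normalised) attribute
#'   units.
#' @param metric `"euclidean"`, `"manhattan"`, or `"chebyshev"`.
#' @param normalize min-max normalise numeric attribute columns so a single
#'   `delta` is meaningful across attributes (default TRUE).
#' @return an object of class `neighborhood_system`.
#' @export
neighborhood_system <- function(ds, delta = 0.15,
                                metric = c("euclidean", "manhattan",
                                           "chebyshev"),
                                normalize = TRUE) {
  stopifnot(inherits(ds, "decision_system"))
  metric <- match.arg(metric)
  if (delta < 0) stop("delta must be non-negative")
  base <- ds
  if (normalize) {
    base$attributes[] <- lapply(base$attributes, function(col) {
      if (!is.numeric(col)) return(col)
      rng <- range(col)
      if (rng[2] - rng[1] <= 0) return(col * 0)
      (col - rng[1]) / (rng[2] - rng[1])
    })
  }
  structure(list(base = base, delta = delta, metric = metric,
                 normalized = normalize),
            class = "neighborhood_system")
}

# Per-attribute coordinate difference: absolute difference for numeric
# columns, 0/1 mismatch for categorical ones.
attr_diffs <- function(ds, xi, yi, B) {
  vapply(B, function(a) {
    col <- ds$attributes[[a]]
    if (is.numeric(col)) abs(col[xi] - col[yi])
    else as.numeric(as.character(col[xi]) != as.character(col[yi]))
  }, numeric(1))
}

combine_metric <- function(d, metric) {
  switch(metric,
         euclidean = sqrt(sum(d^2)),
         manhattan = sum(d),
         chebyshev = if (length(d)) max(d) else 0)
}

#' Distance between two objects on an attribute subset
#'
#' @param ds a [decision_system()].
#' @param x,y object ids.
#' @param B non-empty attribute names.
#' @param metric `"euclidean"`, `"manhattan"`, or `"chebyshev"`.
#' @return the metric distance between the `B`-restricted value vectors.
#' @export
attr_distance <- function(ds, x, y, B,
                          metric = c("euclidean", "manhattan", "chebyshev")) {
  metric <- match.arg(metric)
  check_attrs(ds, B)
  if (length(B) == 0) stop("B must be non-empty")
  xi <- match(x, ds$ids); yi <- match(y, ds$ids)
  if (is.na(xi) || is.na(yi)) stop("unknown object id")
  combine_metric(attr_diffs(ds, xi, yi, B), metric)
}

# All pairwise distances on B, n x n matrix.  B empty -> all zero
# (the whole-universe neighborhood).
distance_matrix <- function(ns, B) {
  ds <- ns$base
  n <- length(ds$ids)
  if (length(B) == 0) return(matrix(0, n, n))
  per <- lapply(B, function(a) {
    col <- ds$attributes[[a]]
    if (is.numeric(col)) abs(outer(col, col, `-`))
    else outer(as.character(col), as.character(col), `!=`) * 1
  })
  switch(ns$metric,
    euclidean = sqrt(Reduce(`+`, lapply(per, function(m) m^2))),
    manhattan = Reduce(`+`, per),
    chebyshev = Reduce(pmax, per))
}

#' delta-neighborhood of an object
#'
#' All objects within metric distance `delta` of `x` on the attribute
#' subset `B`; always contains `x` itself.
#'
#' @param ns a [neighborhood_system()].
#' @param x object id.
#' @param B attribute names (empty set: the neighborhood is the whole
#'   universe).
#' @return character vector of object ids.
#' @export
delta_neighborhood <- function(ns, x, B) {
  ds <- ns$base
  xi <- match(x, ds$ids)
  if (is.na(xi)) stop("unknown object id")
  D <- distance_matrix(ns, B)
  ds$ids[D[xi, ] <= ns$delta + 1e-12]
}

#' Neighborhood lower/upper approximations and regions
#'
#' `lower = {x : N_B(x) subset of X}`, `upper = {x : N_B(x) meets X}`;
#' the positive region is the union of lower approximations over the
#' decision classes, the boundary the union of uppers minus the positive
#' region.
#'
#' @param ns a [neighborhood_system()].
#' @param B attribute names.
#' @param X object-id subset of the universe.
#' @return list with `lower`, `upper`, `positive`, `boundary`.
#' @export
nbd_approximations <- function(ns, B, X) {
  ds <- ns$base
  if (length(setdiff(X, ds$ids))) stop("X must be a subset of the universe")
  D <- distance_matrix(ns, B)
  inX <- ds$ids %in% X
  nb <- D <= ns$delta + 1e-12            # nb[i, j]: j in N(i)
  lower <- ds$ids[apply(nb, 1, function(r) all(inX[r]))]
  upper <- ds$ids[apply(nb, 1, function(r) any(inX[r]))]
  classes <- unique(ds$decision)
  lowers <- lapply(classes, function(cl) {
    incl <- ds$decision == cl
    ds$ids[apply(nb, 1, function(r) all(incl[r]))]
  })
  uppers <- lapply(classes, function(cl) {
    incl <- ds$decision == cl
    ds$ids[apply(nb, 1, function(r) any(incl[r]))]
  })
  positive <- sort_ids(ds, unlist(lowers))
  boundary <- sort_ids(ds, setdiff(unique(unlist(uppers)), positive))
  list(lower = lower, upper = upper, positive = positive,
       boundary = boundary)
}

#' Neighborhood conditional information entropy
#'
#' \deqn{H(D \mid B) = -\frac{1}{|U|} \sum_{x \in U}
#'       \log_2 \frac{|N_B(x) \cap [x]_D|}{|N_B(x)|}}
#' the average log-uncertainty of the decision within each object's
#' neighborhood.  The ratio lies in `(0, 1]` because `x` belongs to both
#' sets, so the entropy is finite and non-negative; it is 0 exactly when
#' every neighborhood is decision-pure.
#'
#' @param ns a [neighborhood_system()].
#' @param B attribute names (empty set: whole-universe neighborhoods).
#' @return `H(D | B) >= 0` in bits.
#' @export
cie <- function(ns, B) {
  ds <- ns$base
  D <- distance_matrix(ns, B)
  nb <- D <= ns$delta + 1e-12
  same_dec <- outer(ds$decision, ds$decision, `==`)
  ratios <- rowSums(nb & same_dec) / rowSums(nb)
  -mean(log2(ratios))
}

#' Neighborhood attribute importance
#'
#' `H(D | B) - H(D | B + a)`: the entropy reduction achieved by adding
#' attribute `a` to the conditioning set.  For `B` empty the conditioning
#' term uses the whole-universe neighborhood.
#'
#' @param ns a [neighborhood_system()].
#' @param B attribute names not containing `a`.
#' @param a candidate attribute name.
#' @return real (may be negative: shrinking neighborhoods need not reduce
#'   entropy).
#' @export
nbd_importance <- function(ns, B, a) {
  if (a %in% B) stop("attribute ", a, " already belongs to B")
  check_attrs(ns$base, c(B, a))
  cie(ns, B) - cie(ns, c(B, a))
}

#' NBD-RS attribute reduction
#'
#' Greedy forward selection on neighborhood conditional entropy.  The
#' conditional entropy of the FULL attribute set is computed first and
#' serves as the stopping reference: starting from the empty set, the
#' attribute with maximal importance with respect to the growing reduct
#' is added (lowest-index tie-break) until the reduct's entropy is within
#' `epsilon` of the full set's, so the returned reduct always preserves
#' the full set's entropy to that tolerance.  Because neighborhood
#' entropy is not monotone in the attribute set, stopping on the
#' individual importances instead could stall above the full-set entropy;
#' anchoring the stop to the full-set value cannot.
#'
#' @param ns a [neighborhood_system()].
#' @param epsilon non-negative entropy-gap tolerance.
#' @return character vector of selected attribute names (empty when the
#'   empty conditioning set is already within `epsilon`).
#' @export
nbd_rs_reduce <- function(ns, epsilon = 0) {
  if (epsilon < 0) stop("epsilon must be non-negative")
  attrs <- ns$base$attrs
  h_full <- cie(ns, attrs)
  reduct <- character(0)
  pool <- attrs
  h_cur <- cie(ns, reduct)
  while (length(pool) > 0 && h_cur - h_full > epsilon + 1e-12) {
    imp <- vapply(pool, function(a) h_cur - cie(ns, c(reduct, a)), numeric(1))
    k <- which.max(imp)
    reduct <- c(reduct, pool[k])
    h_cur <- h_cur - imp[k]
    pool <- pool[-k]
  }
  reduct
}
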