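# Population-level analysis of fitted Exwald parameters: principal axes of
# the (log10 mu, log10 lam, log10 tau) cloud, convex hulls of its 2D
# projections, and prediction curves traced along the first principal axis.

.cloud_matrix <- function(cloud) {
  if (is.data.frame(cloud)) {
    need <- c("mu", "lam", "tau")
    if (!all(need %in% names(cloud))) {
      stop("parameter cloud needs columns mu, lam, tau")
    }
    ids <- if ("record_id" %in% names(cloud)) as.character(cloud$record_id)
           else sprintf("r%03d", seq_len(nrow(cloud)))
    m <- as.matrix(cloud[, need])
  } else {
    m <- as.matrix(cloud)
    if (ncol(m) != 3) stop("parameter cloud must have 3 columns (mu, lam, tau)")
    colnames(m) <- c("mu", "lam", "tau")
    ids <- if (!is.null(rownames(m))) rownames(m) else sprintf("r%03d", seq_len(nrow(m)))
  }
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive parameter in record '%s' (%s)",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  list(m = m, ids = ids)
}

#' Principal component analysis of Exwald parameters in log space
#'
#' Centers the base-10 logs of the per-record (mu, lam, tau) triples and
#' eigendecomposes their covariance matrix (no per-axis rescaling, matching
#' equal-decade log-log axes).  The first axis parameterizes the
#' regular-to-irregular continuum; its sign is fixed so that the log-tau
#' loading is positive (increasing score = more irregular firing).
#'
#' @param cloud data frame with columns `mu`, `lam`, `tau` (ms; optionally
#'   `record_id`), or a 3-column matrix; at least 3 records, all positive.
#' @return object of class `"isi_pca"`: `center` (mean log10 parameters),
#'   `axes` (3 x 3 orthonormal loadings, columns ordered by variance),
#'   `variance_fractions`, `scores` (records x axes), `record_ids`.
#' @export
log_pca <- function(cloud) {
  cm <- .cloud_matrix(cloud)
  if (nrow(cm$m) < 3) stop("need at least 3 records for PCA")
  L <- log10(cm$m)
  pr <- stats::prcomp(L, center = TRUE, scale. = FALSE)
  axes <- pr$rotation
  scores <- pr$x
  # deterministic sign convention: PC1 has positive tau loading; the
  # remaining axes take their largest-magnitude loading positive
  flip <- numeric(3)
  flip[1] <- if (axes["tau", 1] < 0) -1 else 1
  for (j in 2:3) {
    k <- which.max(abs(axes[, j]))
    flip[j] <- if (axes[k, j] < 0) -1 else 1
  }
  axes <- sweep(axes, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(center = colMeans(L), axes = axes,
                 variance_fractions = vf, scores = scores,
                 record_ids = cm$ids),
            class = "isi_pca")
}

#' @export
print.isi_pca <- function(x, ...) {
  cat(sprintf("<isi_pca> %d records; variance fractions %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_fractions), collapse = " / ")))
  cat("PC1 loadings (log10 mu, lam, tau):",
      paste(sprintf("%.3f", x$axes[, 1]), collapse = ", "), "\n")
  invisible(x)
}

#' Convex hull of a 2D projection of the parameter cloud
#'
#' The smallest polygon enclosing all points of the chosen log-log
#' projection, with vertices returned in counterclockwise order.
#'
#' @param cloud as in [log_pca()].
#' @param plane length-2 character vector naming the projection, e.g.
#'   `c("tau", "lam")`; coordinates are base-10 logs.
#' @return object of class `"hull_polygon"`: `plane`, `vertices` (matrix of
#'   hull points, counterclockwise), `index` (rows of the input on the
#'   hull), `degenerate` (TRUE when all points are collinear, in which case
#'   the two extreme points are returned).
#' @export
convex_hull_2d <- function(cloud, plane = c("tau", "lam")) {
  cm <- .cloud_matrix(cloud)
  plane <- match.arg(plane, c("mu", "lam", "tau"), several.ok = TRUE)
  if (length(plane) != 2 || plane[1] == plane[2]) {
    stop("plane must name two distinct parameters")
  }
  pts <- log10(cm$m[, plane, drop = FALSE])
  if (nrow(pts) < 3) stop("need at least 3 points for a hull")
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  v <- pts[idx, , drop = FALSE]
  # signed area; chull() returns clockwise order, flip to counterclockwise
  n <- nrow(v)
  area2 <- sum(v[, 1] * v[c(2:n, 1), 2] - v[c(2:n, 1), 1] * v[, 2])
  degenerate <- FALSE
  if (abs(area2) < 1e-12 || n < 3) {
    # collinear: keep the two extreme points along the spread direction
    d <- pts[, 1] + pts[, 2] * 0
    span <- order(pts[, 1], pts[, 2])
    idx <- c(span[1], span[length(span)])
    v <- pts[idx, , drop = FALSE]
    degenerate <- TRUE
  } else if (area2 < 0) {
    idx <- rev(idx)
    v <- pts[idx, , drop = FALSE]
  }
  structure(list(plane = plane, vertices = v, index = idx,
                 degenerate = degenerate),
            class = "hull_polygon")
}

#' Exwald model at a point on the first principal axis
#'
#' @param pca an `"isi_pca"`.
#' @param s arclength coordinate (score) along PC1, in log10 units.
#' @return named vector (mu, lam, tau), always strictly positive.
#' @export
pc1_model_at <- function(pca, s) {
  stopifnot(inherits(pca, "isi_pca"), is.numeric(s), length(s) == 1)
  p <- 10^(pca$center + s * pca$axes[, 1])
  names(p) <- names(pca$center)
  p
}

.pc1_statistics <- c("mean_isi", "cv", "tau", "lam", "mu")

.stat_of_params <- function(stat, p) {
  switch(stat,
    mean_isi = p[["mu"]] + p[["tau"]],
    cv = {
      m <- exwald_moments(p[["mu"]], p[["lam"]], p[["tau"]])
      m[["cv"]]
    },
    tau = p[["tau"]],
    lam = p[["lam"]],
    mu = p[["mu"]],
    stop("unsupported statistic: ", stat))
}

#' Predict one statistic from another along the first principal axis
#'
#' For each requested value of `statistic_in`, finds the PC1 arclength at
#' which the Exwald model on the axis attains that value (bisection within
#' the observed score range extended by 20 percent on each side), then
#' evaluates `statistic_out` for the same model.  This projects the
#' population's principal axis into, e.g., the mean-ISI/CV plane.
#'
#' @param pca an `"isi_pca"` fitted to an (mu, lam, tau) cloud.
#' @param statistic_in,statistic_out one of `"mean_isi"`, `"cv"`, `"tau"`,
#'   `"lam"`, `"mu"`.
#' @param grid values of `statistic_in` at which to evaluate the curve.
#' @return data frame with columns named after the two statistics plus the
#'   solved coordinate `s`; grid values unattainable on the axis segment are
#'   omitted with a warning.
#' @export
pc1_curve <- function(pca, statistic_in, statistic_out, grid) {
  stopifnot(inherits(pca, "isi_pca"))
  statistic_in <- match.arg(statistic_in, .pc1_statistics)
  statistic_out <- match.arg(statistic_out, .pc1_statistics)
  r <- range(pca$scores[, 1])
  pad <- 0.2 * diff(r)
  lo <- r[1] - pad
  hi <- r[2] + pad
  sgrid <- seq(lo, hi, length.out = 512)
  f_in <- vapply(sgrid, function(s) .stat_of_params(statistic_in, pc1_model_at(pca, s)),
                 numeric(1))
  rows <- lapply(grid, function(target) {
    dif <- f_in - target
    ix <- which(dif[-1] * dif[-length(dif)] <= 0)
    if (!length(ix)) return(NULL)
    root <- stats::uniroot(
      function(s) .stat_of_params(statistic_in, pc1_model_at(pca, s)) - target,
      lower = sgrid[ix[1]], upper = sgrid[ix[1] + 1], tol = 1e-12)
    p <- pc1_model_at(pca, root$root)
    out <- data.frame(in_value = target,
                      out_value = .stat_of_params(statistic_out, p),
                      s = root$root)
    out
  })
  missing <- vapply(rows, is.null, logical(1))
  if (any(missing)) {
    warning(sprintf("%d grid value(s) of %s not attainable on the PC1 segment; omitted",
                    sum(missing), statistic_in))
  }
  out <- do.call(rbind, rows[!missing])
  if (is.null(out)) {
    out <- data.frame(in_value = numeric(), out_value = numeric(), s = numeric())
  }
  names(out)[1:2] <- c(statistic_in, statistic_out)
  out
}
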