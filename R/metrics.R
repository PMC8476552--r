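# Validation and concordance statistics: overlap, surface distance,
# intraclass correlation, Pearson correlation, Mann-Whitney U, and the
# threshold-sweep correlation profile.

#' Dice overlap coefficient
#'
#' @param a,b logical arrays on the same grid.
#' @return `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks are not on the same grid")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Maximum symmetric surface distance (Hausdorff) between meshes
#'
#' Vertex-to-surface distances (point-to-triangle, not point-to-vertex, so
#' the measure is not inflated by mesh resolution), symmetrized by taking
#' the larger directed maximum.
#'
#' @param a,b [surface_mesh()] objects.
#' @return Distance in mm.
#' @export
max_surface_distance <- function(a, b) {
  stopifnot(inherits(a, "surface_mesh"), inherits(b, "surface_mesh"))
  if (nrow(a$vertices) == 0L || nrow(b$vertices) == 0L)
    stop("empty mesh")
  dab <- max(cpp_point_mesh_dist(a$vertices, b$vertices, b$faces))
  dba <- max(cpp_point_mesh_dist(b$vertices, a$vertices, a$faces))
  max(dab, dba)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` from the two-way
#' ANOVA mean squares of an n subjects x k raters matrix.
#'
#' @param ratings numeric matrix, n >= 3 rows (subjects), k >= 2 columns
#'   (raters), finite entries.
#' @return The ICC estimate; `NA` with a warning when the ratings have no
#'   variance at all.
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3L || k < 2L)
    stop("need at least 3 subjects and 2 raters")
  if (any(!is.finite(ratings)))
    stop("ratings must be finite")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-300) {
    warning("ratings have zero variance; ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' U from midrank sums. The p-value is exact (full enumeration of the
#' `choose(n1+n2, n1)` group assignments) for `n1 + n2 <= 12` without ties,
#' and a normal approximation with tie correction and continuity correction
#' otherwise. Two-sided.
#'
#' @param g1,g2 numeric vectors (both non-empty).
#' @return A list with `U` (statistic of the first group), `p`, `method`.
#' @export
mann_whitney_u <- function(g1, g2) {
  if (!length(g1) || !length(g2)) stop("empty group")
  n1 <- length(g1)
  n2 <- length(g2)
  all_v <- c(g1, g2)
  rk <- rank(all_v)
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_v))
  if (n1 + n2 <= 12L && !ties) {
    combs <- combn(n1 + n2, n1)
    rk_sorted <- seq_len(n1 + n2)
    us <- colSums(matrix(rk_sorted[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U1 - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(all_v)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr)
    z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U1, p = min(p, 1), method = method)
}

#' Correlation profile across transmurality thresholds
#'
#' Applies [pearson_r()] between each column of a per-subject area table
#' (columns = thresholds) and a per-subject outcome, and reports the
#' threshold with the largest absolute correlation.
#'
#' @param areas numeric matrix or data.frame, subjects x thresholds, with
#'   threshold values as (numeric-convertible) column names.
#' @param outcome numeric per-subject outcome (e.g. VT cycle length in ms).
#' @return A list with `profile` (data.frame threshold, r, p) and
#'   `best_threshold` (threshold maximizing |r|).
#' @export
threshold_sweep_correlation <- function(areas, outcome) {
  areas <- as.matrix(areas)
  if (nrow(areas) != length(outcome))
    stop("areas and outcome must describe the same subjects")
  if (nrow(areas) < 3L) stop("need at least 3 subjects")
  taus <- suppressWarnings(as.numeric(colnames(areas)))
  if (any(is.na(taus))) taus <- seq_len(ncol(areas))
  prof <- do.call(rbind, lapply(seq_len(ncol(areas)), function(j) {
    res <- tryCatch(
      suppressWarnings(pearson_r(areas[, j], outcome)),
      error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(threshold = taus[j], r = res$r, p = res$p)
  }))
  best <- prof$threshold[which.max(abs(prof$r))]
  list(profile = prof, best_threshold = best)
}

#' Concordance between two transmurality maps
#'
#' Matches every valid vertex of the reference mesh to its nearest valid
#' vertex on the test mesh and reports agreement of the per-vertex
#' transmurality (and optionally thickness) values: ICC(2,1) and Pearson r.
#'
#' @param map_ref,mesh_ref reference [transmurality_map()] and its mesh.
#' @param map_test,mesh_test test map and mesh.
#' @param value column to compare (`"tsm"`, `"wall_thickness"` or
#'   `"scar_thickness"`).
#' @return A list with `icc`, `r`, `p`, `n`, and the matched `ratings`
#'   matrix.
#' @export
map_concordance <- function(map_ref, mesh_ref, map_test, mesh_test,
                            value = c("tsm", "wall_thickness",
                                      "scar_thickness")) {
  value <- match.arg(value)
  vr <- map_ref$valid
  vt <- map_test$valid
  if (sum(vr) < 3L || sum(vt) < 3L)
    stop("need at least 3 valid vertices per map")
  A <- mesh_ref$vertices[vr, , drop = FALSE]
  B <- mesh_test$vertices[vt, , drop = FALSE]
  idx <- cpp_nearest_point(A, B)
  ratings <- cbind(reference = map_ref[[value]][vr],
                   test = map_test[[value]][vt][idx])
  pr <- suppressWarnings(pearson_r(ratings[, 1], ratings[, 2]))
  list(icc = icc_2_1(ratings), r = pr$r, p = pr$p, n = nrow(ratings),
       ratings = ratings)
}
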