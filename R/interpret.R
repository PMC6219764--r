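#' Per-subregion class score maps from final-layer features
#'
#' Applies the linear classification head to every cell of the final
#' convolutional feature grid: for class c and grid cell (i, j),
#' `Y[c, i, j] = sum_k B[c, k] * X[k, i, j] + B0[c]`. Because the head acts
#' on globally average-pooled features, the grid-average of each class's
#' map equals the model's logit for that class.
#'
#' @param features List with `X` (`K x g x g` activation array), as
#'   returned by [extract_final_features()].
#' @param B `n_classes x K` head weight matrix (or take both `B` and `B0`
#'   from `features` by default).
#' @param B0 Length-`n_classes` intercept vector.
#' @return `n_classes x g x g` score array (rows named by class).
#' @export
subregion_scores <- function(features, B = features$B, B0 = features$B0) {
  X <- features$X
  d <- dim(X)
  stopifnot(length(d) == 3L, is.matrix(B), length(B0) == nrow(B))
  if (ncol(B) != d[1])
    stop(sprintf("channel mismatch: features have K = %d, head has K = %d",
                 d[1], ncol(B)))
  Y <- B %*% matrix(X, d[1], d[2] * d[3]) + B0
  dim(Y) <- c(nrow(B), d[2], d[3])
  dimnames(Y) <- list(rownames(B), NULL, NULL)
  Y
}

#' Cellwise softmax probability map for a target class
#'
#' At every grid cell, the class scores are passed through a softmax and
#' the target class's probability is returned; each cell's probabilities
#' over all classes sum to 1.
#'
#' @param scores `n_classes x g x g` score array from [subregion_scores()].
#' @param target Class index or name.
#' @return `g x g` matrix of probabilities in `[0, 1]`.
#' @export
subregion_probability <- function(scores, target) {
  d <- dim(scores)
  stopifnot(length(d) == 3L)
  if (d[1] < 2L) stop("softmax requires at least two classes")
  if (is.character(target)) {
    target <- match(target, dimnames(scores)[[1]])
    if (is.na(target)) stop("unknown target class")
  }
  Z <- matrix(scores, d[1], d[2] * d[3])
  Z <- exp(sweep(Z, 2L, apply(Z, 2L, max)))
  P <- Z[target, ] / colSums(Z)
  matrix(P, d[2], d[3])
}

#' Count decisive subregions
#'
#' Number of grid cells whose probability for the target class meets or
#' exceeds the threshold (inclusive at exactly `tau`).
#'
#' @param P `g x g` probability map from [subregion_probability()].
#' @param tau Decisiveness threshold in (0, 1); default 0.95.
#' @return Integer count in `[0, g^2]`.
#' @export
count_decisive <- function(P, tau = 0.95) {
  stopifnot(tau > 0, tau < 1)
  sum(P >= tau)
}

#' Influence heatmap: target evidence minus all other classes
#'
#' Computes `D[i, j] = Y[target, i, j] - sum_other Y[c, i, j]`, then
#' subtracts the grid mean so the map sums to zero -- highlighting the
#' subregions whose evidence for the target class stands out even when
#' many subregions contribute positively.
#'
#' @param scores `n_classes x g x g` score array.
#' @param target Class index or name.
#' @return `g x g` zero-mean matrix.
#' @export
influence_heatmap <- function(scores, target) {
  d <- dim(scores)
  stopifnot(length(d) == 3L, d[1] >= 2L)
  if (is.character(target)) {
    target <- match(target, dimnames(scores)[[1]])
    if (is.na(target)) stop("unknown target class")
  }
  D <- scores[target, , ] -
    apply(scores[-target, , , drop = FALSE], c(2, 3), sum)
  D - mean(D)
}

#' Decisive-subregion statistics over an image set
#'
#' For each image, counts the grid cells that individually predict the
#' target class with probability at least `tau`, and summarizes the counts
#' (mean, min, max, and the mean as a fraction of the `g^2` cells).
#'
#' @param model A trained multiclass `cnn_classifier`.
#' @param images `size x size x n` array.
#' @param target Class name or index whose probability is thresholded.
#' @param tau Decisiveness threshold.
#' @return An object of class `decisive_summary`: `counts` (per image),
#'   `mean`, `min`, `max`, `cells` (`g^2`), and `fraction`
#'   (`mean / cells`).
#' @export
summarize_decisive <- function(model, images, target, tau = 0.95) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  n <- dim(images)[3]
  stopifnot(n >= 1)
  counts <- integer(n)
  for (i in seq_len(n)) {
    ft <- extract_final_features(model, images[, , i])
    P <- subregion_probability(subregion_scores(ft), target)
    counts[i] <- count_decisive(P, tau)
  }
  g2 <- ft$g^2
  structure(list(counts = counts, mean = mean(counts),
                 min = min(counts), max = max(counts),
                 cells = g2, fraction = mean(counts) / g2, tau = tau),
            class = "decisive_summary")
}

#' @exportS3Method base::print
print.decisive_summary <- function(x, ...) {
  cat(sprintf("<decisive_summary> mean %.1f / %d cells (%.1f%%), min %d, max %d, tau = %.2f, N = %d\n",
              x$mean, x$cells, 100 * x$fraction, x$min, x$max, x$tau,
              length(x$counts)))
  invisible(x)
}

#' Grid cells covered by a site's corner token
#'
#' Maps a profile's token block onto the `g x g` final feature grid of an
#' image of side `image_size`. `token_grid_cell()` returns the cell
#' containing the token's center pixel; `token_grid_cells()` returns every
#' cell the block overlaps -- the region where an influence heatmap should
#' localize when the token drives classification (a token larger than one
#' cell legitimately peaks on any cell it covers).
#'
#' @param profile A [site_profile()] with a token.
#' @param image_size Image side length in pixels.
#' @param g Feature-grid side length.
#' @return `token_grid_cell()`: integer `c(row, col)`;
#'   `token_grid_cells()`: two-column matrix of covered `(row, col)` cells.
#' @export
token_grid_cell <- function(profile, image_size, g) {
  tok <- profile$token
  if (is.null(tok) || tok$intensity <= 0) stop("profile has no token")
  center <- function(anchor) {
    lo <- if (anchor %in% c("t", "l")) tok$margin + 1 else
      image_size - tok$margin - tok$side + 1
    lo + (tok$side - 1) / 2
  }
  px <- c(center(substr(tok$corner, 1, 1)), center(substr(tok$corner, 2, 2)))
  pmin(g, pmax(1, ceiling(px / (image_size / g))))
}

#' @rdname token_grid_cell
#' @export
token_grid_cells <- function(profile, image_size, g) {
  tok <- profile$token
  if (is.null(tok) || tok$intensity <= 0) stop("profile has no token")
  span <- function(anchor) {
    lo <- if (anchor %in% c("t", "l")) tok$margin + 1 else
      image_size - tok$margin - tok$side + 1
    px <- lo:(lo + tok$side - 1)
    unique(pmin(g, pmax(1, ceiling(px / (image_size / g)))))
  }
  rows <- span(substr(tok$corner, 1, 1))
  cols <- span(substr(tok$corner, 2, 2))
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Export a heatmap as a PNG overlay and a numeric CSV
#'
#' @param heatmap `g x g` numeric matrix.
#' @param path_png,path_csv Output paths (either may be `NULL`).
#' @return Invisibly, the heatmap.
#' @export
write_heatmap <- function(heatmap, path_png = NULL, path_csv = NULL) {
  if (!is.null(path_csv))
    utils::write.csv(heatmap, path_csv, row.names = FALSE)
  if (!is.null(path_png)) {
    rng <- range(heatmap)
    scaled <- if (diff(rng) > 0) (heatmap - rng[1]) / diff(rng) else
      heatmap * 0 + 0.5
    png::writePNG(scaled, path_png)
  }
  invisible(heatmap)
}
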