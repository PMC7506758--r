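# Batch scoring: assemble the M x N x 2 difference matrix over all
# camouflage/background pairs, weight the two metrics by the information
# entropy of their value distributions (a metric that discriminates more
# between alternatives carries more weight), and pool into one
# conspicuousness score per pattern. Low score = effective camouflage.

#' Build the M x N x 2 difference matrix
#'
#' Runs [compute_pair()] for every camouflage/background combination.
#'
#' @param camos,bgs Lists of deviceRGB [raster_image] objects (named lists
#'   supply the ids; unnamed lists get `camo1..M` / `bg1..N`).
#' @param geom A [viewing_geometry()].
#' @param config A [pair_config()].
#' @return A `difference_matrix`: list with `x` (an `M x N x 2` array,
#'   metrics `"icsi"` and `"gmsd"` on the third axis), `camo_ids`,
#'   `bg_ids`, `metric_ids`.
#' @export
build_difference_matrix <- function(camos, bgs,
                                    geom = viewing_geometry(spd = 35),
                                    config = pair_config()) {
  if (length(camos) == 0L || length(bgs) == 0L) {
    stop("need at least one camouflage and one background image")
  }
  camo_ids <- names(camos)
  if (is.null(camo_ids)) camo_ids <- paste0("camo", seq_along(camos))
  bg_ids <- names(bgs)
  if (is.null(bg_ids)) bg_ids <- paste0("bg", seq_along(bgs))
  metric_ids <- c("icsi", "gmsd")
  x <- array(NA_real_,
             dim = c(length(camos), length(bgs), 2L),
             dimnames = list(camo_ids, bg_ids, metric_ids))
  for (i in seq_along(camos)) {
    for (j in seq_along(bgs)) {
      r <- compute_pair(camos[[i]], bgs[[j]], geom, config)
      x[i, j, 1L] <- r$icsi
      x[i, j, 2L] <- r$gmsd
    }
  }
  new_difference_matrix(x, camo_ids, bg_ids, metric_ids)
}

new_difference_matrix <- function(x, camo_ids, bg_ids,
                                  metric_ids = c("icsi", "gmsd")) {
  if (!all(is.finite(x)) || any(x < 0)) {
    stop("difference matrix entries must be finite and non-negative")
  }
  structure(list(x = x, camo_ids = camo_ids, bg_ids = bg_ids,
                 metric_ids = metric_ids),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<difference_matrix> %d camouflages x %d backgrounds x %d metrics\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Entropy weights for the metrics
#'
#' For each metric `k`, the entries are normalized to proportions
#' `p_ijk = x_ijk / sum(x_..k)` and the normalized Shannon entropy
#' `e_k = -(1 / ln(MN)) * sum(p ln p)` is computed (with `0 ln 0 = 0`).
#' Metrics whose values vary more across pairs have lower entropy and
#' receive higher weight `w_k = (1 - e_k) / sum(1 - e)`. A metric that is
#' constant across all pairs (including all-zero) is uninformative and gets
#' weight 0; if every metric is uninformative, equal weights are returned
#' with a warning.
#'
#' @param x A `difference_matrix` (or a bare `M x N x K` array) with
#'   `M * N >= 2`.
#' @return Named numeric weight vector in `[0, 1]` summing to 1.
#' @export
entropy_weights <- function(x) {
  arr <- if (inherits(x, "difference_matrix")) x$x else x
  if (!is.array(arr) || length(dim(arr)) != 3L) {
    stop("expected an M x N x K array or difference_matrix")
  }
  d <- dim(arr)
  n_cells <- d[1L] * d[2L]
  if (n_cells < 2L) {
    warning("entropy weights undefined for a single cell; using equal weights")
    w <- rep(1 / d[3L], d[3L])
    names(w) <- dimnames(arr)[[3L]]
    return(w)
  }
  divergence <- vapply(seq_len(d[3L]), function(k) {
    slice <- arr[, , k]
    total <- sum(slice)
    if (total <= 0 || max(slice) == min(slice)) return(0) # uninformative
    p <- slice / total
    e <- -sum(ifelse(p > 0, p * log(p), 0)) / log(n_cells)
    1 - e
  }, 0)
  if (sum(divergence) <= 0) {
    warning("all metrics uniform across pairs; falling back to equal weights")
    w <- rep(1 / d[3L], d[3L])
  } else {
    w <- divergence / sum(divergence)
  }
  names(w) <- if (inherits(x, "difference_matrix")) x$metric_ids
              else dimnames(arr)[[3L]]
  w
}

#' Aggregate the difference matrix into conspicuousness scores
#'
#' Default orientation `per_camouflage`: each camouflage pattern `i` gets
#' `v_i = sum_k w_k * mean_j x[i, j, k]`, the entropy-weighted mean of its
#' color and texture differences over all backgrounds. The transposed
#' `per_background` orientation (mean over camouflages, scoring each
#' background) is also available. Lower score = more effective camouflage.
#'
#' @param x A `difference_matrix`.
#' @param w Weight vector from [entropy_weights()] (length K, sums to 1).
#' @param orientation `"per_camouflage"` or `"per_background"`.
#' @return A `score_report`: data frame with columns `pattern_id`,
#'   `icsi_mean`, `gmsd_mean`, `weight_icsi`, `weight_gmsd`, `score`,
#'   `rank` (rank 1 = lowest score = best camouflage; ties keep input
#'   order), carrying the weights and polarity as attributes.
#' @export
aggregate_scores <- function(x, w = entropy_weights(x),
                             orientation = c("per_camouflage",
                                             "per_background")) {
  orientation <- match.arg(orientation)
  if (!inherits(x, "difference_matrix")) stop("expected a difference_matrix")
  K <- dim(x$x)[3L]
  if (length(w) != K) {
    stop("weight vector length ", length(w), " does not match ", K, " metrics")
  }
  if (abs(sum(w) - 1) > 1e-8 || any(w < -1e-12)) {
    stop("weights must be non-negative and sum to 1")
  }
  margin <- if (orientation == "per_camouflage") 1L else 2L
  ids <- if (margin == 1L) x$camo_ids else x$bg_ids
  metric_means <- sapply(seq_len(K), function(k) {
    apply(x$x[, , k, drop = FALSE], margin, mean)
  })
  metric_means <- matrix(metric_means, nrow = length(ids), ncol = K)
  score <- as.numeric(metric_means %*% w)
  report <- data.frame(pattern_id = ids,
                       icsi_mean = metric_means[, 1L],
                       gmsd_mean = metric_means[, 2L],
                       weight_icsi = w[[1L]],
                       weight_gmsd = w[[2L]],
                       score = score,
                       rank = rank(score, ties.method = "first"),
                       row.names = NULL)
  structure(report, class = c("score_report", "data.frame"),
            weights = w, orientation = orientation,
            polarity = "lower score = more effective camouflage")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Camouflage conspicuousness scores (", attr(x, "polarity"), ")\n",
      sep = "")
  cat(sprintf("orientation: %s; weights: icsi=%.4f gmsd=%.4f\n",
              attr(x, "orientation"), attr(x, "weights")[1L],
              attr(x, "weights")[2L]))
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Absolute Pearson correlation
#'
#' Agreement between objective scores and a subjective performance
#' indicator, reported as `|r|` in `[0, 1]` so that indicators of either
#' polarity (hit rate up vs. detection time down) compare on one scale.
#'
#' @param scores,subjective Numeric vectors of equal length >= 3 with
#'   non-zero variance.
#' @return `|Pearson r|`.
#' @export
pearson_abs <- function(scores, subjective) {
  if (length(scores) != length(subjective)) stop("vectors differ in length")
  if (length(scores) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(scores) == 0 || stats::sd(subjective) == 0) {
    stop("correlation undefined: zero variance in one of the vectors")
  }
  abs(stats::cor(scores, subjective))
}

#' Correlate scores with a subjective response table
#'
#' @param report A `score_report`.
#' @param subjective Data frame with columns `pattern_id` plus one or more
#'   numeric indicator columns (e.g. `hit_rate`, `detection_time`,
#'   `difficulty`); rows are matched to the report by `pattern_id`.
#' @return Named vector of `|Pearson r|` per indicator column.
#' @export
correlate_with_subjective <- function(report, subjective) {
  if (!"pattern_id" %in% names(subjective)) {
    stop("subjective table must have a pattern_id column")
  }
  m <- match(report$pattern_id, subjective$pattern_id)
  if (anyNA(m)) {
    stop("subjective table missing patterns: ",
         paste(report$pattern_id[is.na(m)], collapse = ", "))
  }
  cols <- setdiff(names(subjective), "pattern_id")
  vapply(cols, function(col) {
    pearson_abs(report$score, as.numeric(subjective[[col]][m]))
  }, 0)
}

#' Persist / reload a difference matrix as CSV
#'
#' Long format `camo_id,bg_id,metric,value`, so external tools can
#' re-weight without recomputing the metrics; reloading and re-scoring
#' reproduces the original report exactly.
#'
#' @param x A `difference_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (write) or a `difference_matrix` (read).
#' @export
write_difference_matrix <- function(x, path) {
  if (!inherits(x, "difference_matrix")) stop("expected a difference_matrix")
  long <- expand.grid(camo_id = x$camo_ids, bg_id = x$bg_ids,
                      metric = x$metric_ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(x$x)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_difference_matrix
#' @export
read_difference_matrix <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  camo_ids <- unique(long$camo_id)
  bg_ids <- unique(long$bg_id)
  metric_ids <- unique(long$metric)
  x <- array(NA_real_,
             dim = c(length(camo_ids), length(bg_ids), length(metric_ids)),
             dimnames = list(camo_ids, bg_ids, metric_ids))
  x[cbind(match(long$camo_id, camo_ids), match(long$bg_id, bg_ids),
          match(long$metric, metric_ids))] <- long$value
  new_difference_matrix(x, camo_ids, bg_ids, metric_ids)
}
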