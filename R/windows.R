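# Stepwise-window divergence scan over a multiple alignment: nucleotide
# diversity (Pi), GC content and gap proportion per window, hotspot ranking,
# and the Pi ~ GC / Pi ~ gap regressions.
#
# Pi uses pairwise deletion: each unordered sequence pair is compared only
# at columns where both members carry a base in {A,C,G,T}; the per-pair
# distance is mismatches / compared sites and Pi is the mean over pairs.
# Pairs with no comparable site are dropped (and counted); if every pair is
# dropped Pi is NA, never 0.

#' Enumerate sliding windows over an alignment
#'
#' Windows start at 0, step, 2*step, ...; only full-length windows are
#' emitted, so a trailing stub shorter than `window` is dropped.
#'
#' @param length alignment length in columns
#' @param window window length (default 600)
#' @param step step size (default 200)
#' @return two-column matrix of 0-based half-open `[start, end)` windows
#' @export
sliding_windows <- function(length, window = 600, step = 200) {
  if (window < 1 || step < 1) stop2("window and step must be >= 1")
  starts <- seq(0L, by = as.integer(step), length.out =
                  max(0L, (as.integer(length) - as.integer(window)) %/%
                        as.integer(step) + 1L))
  if (length < window) starts <- integer(0)
  cbind(start = starts, end = starts + as.integer(window))
}

pair_index <- function(n) {
  # all unordered pairs of 1..n as a 2-row matrix
  utils::combn(n, 2)
}

#' Nucleotide diversity of one window
#'
#' @param aln an `alignment_matrix`
#' @param window `c(start, end)` 0-based half-open column interval
#' @return list with `pi` (NA when no pair has comparable sites) and
#'   `n_pairs_used`
#' @export
window_pi <- function(aln, window) {
  cols <- (window[1] + 1L):window[2]
  sub <- aln$mat[, cols, drop = FALSE]
  prs <- pair_index(nrow(sub))
  d <- numeric(0); used <- 0L
  for (k in seq_len(ncol(prs))) {
    a <- sub[prs[1, k], ]; b <- sub[prs[2, k], ]
    comp <- a %in% BASES & b %in% BASES
    m <- sum(comp)
    if (m == 0) next
    used <- used + 1L
    d <- c(d, sum(a[comp] != b[comp]) / m)
  }
  list(pi = if (used == 0) NA_real_ else mean(d), n_pairs_used = used)
}

#' GC content of one window
#'
#' `(G + C) / (A + C + G + T)` over all cells of all rows; NA when the
#' window holds no unambiguous base.
#' @inheritParams window_pi
#' @return numeric fraction in `[0, 1]` or NA
#' @export
window_gc <- function(aln, window) {
  cols <- (window[1] + 1L):window[2]
  gc_fraction(as.vector(aln$mat[, cols, drop = FALSE]))
}

#' Gap proportion of one window
#'
#' Fraction of `-` cells among all cells (rows x window length); N counts
#' as a base cell, not a gap.
#' @inheritParams window_pi
#' @return numeric fraction in `[0, 1]`
#' @export
window_gap <- function(aln, window) {
  cols <- (window[1] + 1L):window[2]
  mean(aln$mat[, cols, drop = FALSE] == "-")
}

#' Stepwise-window scan of an alignment
#'
#' Computes Pi, GC content and gap proportion for every full window, in
#' coordinate order. Implemented with per-pair cumulative counts so the
#' whole-plastome scan is a single pass.
#'
#' @param aln an `alignment_matrix`
#' @param window window length in columns (default 600)
#' @param step step size in columns (default 200)
#' @return data frame (`window_start`, `window_end` 0-based half-open, `pi`,
#'   `gc`, `gap`, `n_pairs_used`)
#' @export
scan_windows <- function(aln, window = 600, step = 200) {
  L <- aln_length(aln)
  win <- sliding_windows(L, window, step)
  if (!nrow(win)) {
    return(data.frame(window_start = integer(0), window_end = integer(0),
                      pi = numeric(0), gc = numeric(0), gap = numeric(0),
                      n_pairs_used = integer(0)))
  }
  mat <- aln$mat
  n <- nrow(mat)
  is_base <- matrix(mat %in% BASES, nrow = n)
  is_gc <- is_base & (mat == "G" | mat == "C")
  is_gap <- mat == "-"

  range_sum <- function(cum, s, e) cum[e + 1L] - cum[s + 1L]  # 0-based [s,e)
  ccum <- function(v) c(0, cumsum(v))

  gc_num <- ccum(colSums(is_gc)); gc_den <- ccum(colSums(is_base))
  gap_cum <- ccum(colSums(is_gap))

  prs <- pair_index(n)
  np <- ncol(prs)
  comp_cum <- mism_cum <- vector("list", np)
  for (k in seq_len(np)) {
    i <- prs[1, k]; j <- prs[2, k]
    comp <- is_base[i, ] & is_base[j, ]
    comp_cum[[k]] <- ccum(comp)
    mism_cum[[k]] <- ccum(comp & (mat[i, ] != mat[j, ]))
  }

  s <- win[, 1]; e <- win[, 2]
  gc <- range_sum(gc_num, s, e) / range_sum(gc_den, s, e)
  gc[range_sum(gc_den, s, e) == 0] <- NA_real_
  gap <- range_sum(gap_cum, s, e) / (n * window)

  used <- integer(nrow(win))
  acc <- numeric(nrow(win))
  for (k in seq_len(np)) {
    m <- range_sum(comp_cum[[k]], s, e)
    x <- range_sum(mism_cum[[k]], s, e)
    ok <- m > 0
    acc[ok] <- acc[ok] + x[ok] / m[ok]
    used <- used + as.integer(ok)
  }
  pi <- ifelse(used > 0, acc / used, NA_real_)

  data.frame(window_start = s, window_end = e, pi = pi, gc = gc, gap = gap,
             n_pairs_used = used)
}

#' Regress transformed Pi on GC content or gap proportion
#'
#' Fits ordinary least squares of `sqrt(pi)` on the predictor (GC
#' untransformed, gap square-root transformed by default, mirroring the
#' usual normalizing transforms for proportions) and reports slope,
#' intercept, Pearson r, r-squared and the two-sided p-value of the slope.
#' Windows with missing Pi or predictor are excluded and counted.
#'
#' @param profiles window table from [scan_windows()]
#' @param predictor `"gc"` or `"gap"`
#' @param transform_pi,transform_predictor transform labels, `"sqrt"` or
#'   `"identity"`; defaults follow the package convention (Pi and gap
#'   square-rooted, GC untransformed)
#' @return one-row data frame (`correlation_result`)
#' @export
correlate_windows <- function(profiles, predictor = c("gc", "gap"),
                              transform_pi = "sqrt",
                              transform_predictor = NULL) {
  predictor <- match.arg(predictor)
  if (is.null(transform_predictor))
    transform_predictor <- if (predictor == "gap") "sqrt" else "identity"
  tf <- function(x, label) switch(label, sqrt = sqrt(x), identity = x,
                                  stop2("unknown transform: ", label))
  y <- tf(profiles$pi, transform_pi)
  x <- tf(profiles[[predictor]], transform_predictor)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop2("fewer than 3 usable windows for correlation")
  fit <- stats::lm(y[keep] ~ x[keep])
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  r <- sign(slope) * sqrt(sm$r.squared)
  p <- if (nrow(sm$coefficients) < 2) NA_real_ else sm$coefficients[2, 4]
  data.frame(predictor = predictor,
             transform = paste0("sqrt(pi)~", transform_predictor, "(",
                                predictor, ")"),
             slope = slope, intercept = unname(stats::coef(fit)[1]),
             r = r, r_squared = sm$r.squared, p_value = p,
             n_windows = sum(keep), n_excluded = sum(!keep),
             stringsAsFactors = FALSE)
}

#' Rank divergence hotspots
#'
#' Windows whose Pi exceeds `threshold` are merged into maximal runs of
#' overlapping or adjacent windows; each run is labeled with the named
#' regions it overlaps (when a region map is supplied) and runs are sorted
#' by peak Pi, descending.
#'
#' @param profiles window table from [scan_windows()]
#' @param regions optional region map from [classify_regions()]
#' @param threshold Pi threshold (default 0.03, the conventional cutoff for
#'   plastome hotspot reporting)
#' @return data frame (`start`, `end`, `peak_pi`, `mean_pi`, `n_windows`,
#'   `regions`)
#' @export
rank_hotspots <- function(profiles, regions = NULL, threshold = 0.03) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      peak_pi = numeric(0), mean_pi = numeric(0),
                      n_windows = integer(0), regions = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(profiles)) return(empty)
  hot <- profiles[!is.na(profiles$pi) & profiles$pi > threshold, , drop = FALSE]
  if (!nrow(hot)) return(empty)
  hot <- hot[order(hot$window_start), , drop = FALSE]
  runs <- list()
  cur <- hot[1, ]
  cur_pis <- cur$pi
  for (i in seq_len(nrow(hot))[-1]) {
    if (hot$window_start[i] <= cur$window_end) {
      cur$window_end <- max(cur$window_end, hot$window_end[i])
      cur_pis <- c(cur_pis, hot$pi[i])
    } else {
      runs[[length(runs) + 1L]] <- list(row = cur, pis = cur_pis)
      cur <- hot[i, ]; cur_pis <- cur$pi
    }
  }
  runs[[length(runs) + 1L]] <- list(row = cur, pis = cur_pis)
  out <- do.call(rbind, lapply(runs, function(r) {
    lab <- ""
    if (!is.null(regions) && nrow(regions)) {
      ov <- regions$end > r$row$window_start & regions$start < r$row$window_end
      lab <- paste(unique(regions$name[ov]), collapse = ",")
    }
    data.frame(start = r$row$window_start, end = r$row$window_end,
               peak_pi = max(r$pis), mean_pi = mean(r$pis),
               n_windows = length(r$pis), regions = lab,
               stringsAsFactors = FALSE)
  }))
  out[order(-out$peak_pi), , drop = FALSE]
}
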