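#' Build a binned wingbeat frequency distribution
#'
#' Peak frequencies from all 20 ms windows are binned at 5 Hz on fixed
#' edges anchored at \code{range[1]}, and normalized by the total number of
#' in-range instances so the probability masses sum to 1. Frequencies
#' outside the range are counted and reported, never silently binned.
#'
#' @param frequencies Numeric vector of per-window frequencies in Hz.
#' @param bin_width Bin width in Hz (default 5).
#' @param range Two-element numeric \code{c(lo, hi)} in Hz (default
#'   \code{c(200, 700)}, the typical female band).
#' @param label Species or trace identifier.
#' @return An object of class \code{freq_distribution} with fields
#'   \code{label}, \code{bin_edges}, \code{counts}, \code{prob_mass},
#'   \code{n_samples} and \code{n_out_of_range}.
#' @export
build_distribution <- function(frequencies, bin_width = 5,
                               range = c(200, 700), label = "unlabelled") {
  stopifnot(is.numeric(frequencies), bin_width > 0,
            length(range) == 2, range[1] < range[2])
  frequencies <- frequencies[is.finite(frequencies)]
  edges <- seq(range[1], range[2], by = bin_width)
  if (abs(edges[length(edges)] - range[2]) > 1e-9)
    stop("range must span a whole number of bins", call. = FALSE)
  in_range <- frequencies >= range[1] & frequencies < range[2]
  n_out <- sum(!in_range)
  f <- frequencies[in_range]
  if (length(f) == 0L)
    stop("empty distribution: no frequencies inside [",
         range[1], ", ", range[2], ") Hz", call. = FALSE)
  idx <- findInterval(f, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(label = label, bin_edges = edges, counts = counts,
         prob_mass = counts / sum(counts), n_samples = sum(counts),
         n_out_of_range = n_out),
    class = "freq_distribution")
}

#' @export
print.freq_distribution <- function(x, ...) {
  s <- distribution_summary(x)
  cat(sprintf(
    "<freq_distribution> %s: n=%d, mean %.1f Hz, q5-q95 [%.1f, %.1f] Hz\n",
    x$label, x$n_samples, s$mean, s$q5, s$q95))
  invisible(x)
}

check_same_bins <- function(p, q) {
  stopifnot(inherits(p, "freq_distribution"), inherits(q, "freq_distribution"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      any(abs(p$bin_edges - q$bin_edges) > 1e-9))
    stop("binning mismatch: distributions must share identical bin edges",
         call. = FALSE)
  invisible(TRUE)
}

#' Bhattacharyya coefficient between two frequency distributions
#'
#' The sum over bins of the geometric mean of the two probability masses,
#' \eqn{\sum_i \sqrt{p_i q_i}}: 1 for identical distributions, 0 for
#' distributions with disjoint support.
#'
#' @param p,q \code{freq_distribution} objects on identical bin edges.
#' @return A scalar in \code{[0, 1]}.
#' @export
bhattacharyya_coefficient <- function(p, q) {
  check_same_bins(p, q)
  min(1, sum(sqrt(p$prob_mass * q$prob_mass)))
}

#' Jensen-Shannon divergence between two frequency distributions
#'
#' The bounded Jensen-Shannon distance with base-2 logarithms,
#' \eqn{\sqrt{\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)}} with
#' \eqn{m = (p+q)/2}: 0 for identical distributions, 1 for disjoint
#' supports. Zero-mass bins contribute nothing by the
#' \eqn{0 \log 0 = 0} convention.
#'
#' @param p,q \code{freq_distribution} objects on identical bin edges.
#' @return A scalar in \code{[0, 1]}.
#' @export
jensen_shannon_divergence <- function(p, q) {
  check_same_bins(p, q)
  pm <- p$prob_mass; qm <- q$prob_mass
  m <- (pm + qm) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(max(0, min(1, (kl(pm, m) + kl(qm, m)) / 2)))
}

#' Summarize a frequency distribution
#'
#' Mean, median, 5th and 95th percentiles and their spread, computed from
#' bin centers weighted by probability mass (discrete weighted quantiles, so
#' a single-occupied-bin distribution has zero spread).
#'
#' @param d A \code{freq_distribution}.
#' @return A list with \code{mean}, \code{median}, \code{q5}, \code{q95}
#'   and \code{spread} (all Hz).
#' @export
distribution_summary <- function(d) {
  stopifnot(inherits(d, "freq_distribution"))
  if (d$n_samples < 1L) stop("empty distribution", call. = FALSE)
  centers <- (d$bin_edges[-length(d$bin_edges)] + d$bin_edges[-1]) / 2
  w <- d$prob_mass
  qw <- function(prob) {
    cdf <- cumsum(w)
    centers[which(cdf >= prob - 1e-12)[1]]
  }
  q5 <- qw(0.05); q95 <- qw(0.95)
  list(mean = sum(centers * w), median = qw(0.5),
       q5 = q5, q95 = q95, spread = q95 - q5)
}

#' Subset-size convergence of a reference distribution
#'
#' Draws random subsets (without replacement) of increasing size from the
#' raw per-window frequencies behind a reference distribution, rebins each
#' subset on the parent's edges, and records the mean Bhattacharyya
#' coefficient and Jensen-Shannon divergence to the parent. Used to judge
#' whether a reference population is well-sampled: the curve reports the
#' smallest subset size whose mean BC against the parent exceeds 0.9.
#'
#' @param d Parent \code{freq_distribution}.
#' @param raw_frequencies The raw frequency instances the parent was built
#'   from.
#' @param sizes Increasing integer vector of subset sizes (each \code{<=}
#'   the number of in-range raw frequencies).
#' @param n_reps Replicates per size (default 200).
#' @param seed RNG seed for reproducibility (optional).
#' @return An object of class \code{convergence_curve}: a list with
#'   \code{subset_sizes}, \code{mean_bc}, \code{mean_jsd}, \code{n_reps},
#'   \code{rng_seed} and \code{smallest_converged_size} (smallest size with
#'   mean BC > 0.9, or \code{NA}).
#' @export
subsample_convergence <- function(d, raw_frequencies, sizes, n_reps = 200,
                                  seed = NULL) {
  stopifnot(inherits(d, "freq_distribution"), n_reps >= 1,
            all(diff(sizes) > 0))
  rng <- range(d$bin_edges)
  raw <- raw_frequencies[raw_frequencies >= rng[1] & raw_frequencies < rng[2]]
  if (any(sizes > length(raw)))
    stop("subset size exceeds the number of in-range samples", call. = FALSE)
  with_seed(seed, {
    mean_bc <- mean_jsd <- numeric(length(sizes))
    bw <- d$bin_edges[2] - d$bin_edges[1]
    for (i in seq_along(sizes)) {
      bc <- js <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        sub <- sample(raw, sizes[i], replace = FALSE)
        ds <- build_distribution(sub, bin_width = bw, range = rng,
                                 label = "subset")
        bc[r] <- bhattacharyya_coefficient(ds, d)
        js[r] <- jensen_shannon_divergence(ds, d)
      }
      mean_bc[i] <- mean(bc)
      mean_jsd[i] <- mean(js)
    }
    conv <- sizes[mean_bc > 0.9]
    structure(
      list(subset_sizes = sizes, mean_bc = mean_bc, mean_jsd = mean_jsd,
           n_reps = n_reps, rng_seed = seed,
           smallest_converged_size = if (length(conv)) conv[1] else NA_integer_),
      class = "convergence_curve")
  })
}

#' Write frequency distributions to CSV
#'
#' Long format: columns \code{species}, \code{bin_lo_hz}, \code{bin_hi_hz},
#' \code{count}, \code{prob_mass}, preceded by a comment header recording
#' each species' sample count and the bin range.
#'
#' @param dists A \code{freq_distribution} or list of them.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_distribution_csv <- function(dists, path) {
  if (inherits(dists, "freq_distribution")) dists <- list(dists)
  hdr <- vapply(dists, function(d) {
    sprintf("# %s n_samples=%d range=[%g,%g]", d$label, d$n_samples,
            min(d$bin_edges), max(d$bin_edges))
  }, character(1))
  rows <- do.call(rbind, lapply(dists, function(d) {
    ne <- length(d$bin_edges)
    data.frame(species = d$label, bin_lo_hz = d$bin_edges[-ne],
               bin_hi_hz = d$bin_edges[-1], count = d$counts,
               prob_mass = d$prob_mass)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read frequency distributions from CSV
#'
#' @param path CSV written by \code{\link{write_distribution_csv}}.
#' @return A named list of \code{freq_distribution} objects.
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  out <- lapply(split(df, df$species), function(d) {
    d <- d[order(d$bin_lo_hz), ]
    edges <- c(d$bin_lo_hz, d$bin_hi_hz[nrow(d)])
    structure(
      list(label = d$species[1], bin_edges = edges, counts = d$count,
           prob_mass = if (sum(d$count) > 0) d$count / sum(d$count)
                       else d$prob_mass,
           n_samples = sum(d$count), n_out_of_range = 0L),
      class = "freq_distribution")
  })
  out[unique(df$species)]
}

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}
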