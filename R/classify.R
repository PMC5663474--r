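#' Build a reference library of species frequency distributions
#'
#' @param dists Named list of \code{freq_distribution} objects (>= 2
#'   species) sharing identical bin edges; names default to each
#'   distribution's label.
#' @param epsilon Optional per-bin floor mass added to every bin before
#'   renormalization (default 0, i.e. raw histograms). A small floor makes
#'   summed-likelihood scores less brittle when references are built from
#'   few samples.
#' @param provenance Free-text notes (device, site), optional.
#' @return An object of class \code{reference_library}.
#' @export
reference_library <- function(dists, epsilon = 0, provenance = NULL) {
  stopifnot(is.list(dists), length(dists) >= 2, epsilon >= 0)
  if (is.null(names(dists)) || any(names(dists) == ""))
    names(dists) <- vapply(dists, function(d) d$label, character(1))
  if (anyDuplicated(names(dists)))
    stop("duplicate species names in library", call. = FALSE)
  for (d in dists) check_same_bins(dists[[1]], d)
  if (epsilon > 0) {
    dists <- lapply(dists, function(d) {
      d$prob_mass <- (d$prob_mass + epsilon) / (1 + epsilon * length(d$prob_mass))
      d
    })
  }
  structure(
    list(species = names(dists), distributions = dists,
         bin_edges = dists[[1]]$bin_edges, epsilon = epsilon,
         provenance = provenance),
    class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d species on [%g, %g] Hz, %g Hz bins\n",
              length(x$species), min(x$bin_edges), max(x$bin_edges),
              x$bin_edges[2] - x$bin_edges[1]))
  invisible(x)
}

#' Species-by-country presence matrix
#'
#' Entomological survey records of which species occur in which countries,
#' used by the location filter to winnow classification candidates.
#'
#' @param presence Logical or 0/1 matrix, rows = species, columns =
#'   ISO-3166 country codes. Every row must have at least one present
#'   country.
#' @return An object of class \code{location_matrix}.
#' @export
location_matrix <- function(presence) {
  presence <- as.matrix(presence) > 0
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs species rownames and country colnames",
         call. = FALSE)
  colnames(presence) <- toupper(colnames(presence))
  if (any(rowSums(presence) == 0))
    stop("every species must be present in at least one country",
         call. = FALSE)
  structure(list(presence = presence), class = "location_matrix")
}

#' Read / write a species-by-country presence matrix as CSV
#'
#' Rows are species, columns ISO-3166 country codes, cells 0/1.
#'
#' @param path CSV path.
#' @return \code{read_location_csv}: a \code{\link{location_matrix}}.
#' @export
read_location_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  location_matrix(as.matrix(df))
}

#' @rdname read_location_csv
#' @param matrix A \code{\link{location_matrix}}.
#' @export
write_location_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "location_matrix"))
  utils::write.csv(matrix$presence * 1L, path)
  invisible(path)
}

trace_frequencies <- function(trace) {
  if (inherits(trace, "flight_trace")) trace$frequencies
  else if (is.numeric(trace)) trace
  else stop("expected a flight_trace or a numeric frequency vector",
            call. = FALSE)
}

#' Summed per-window likelihood of a trace under each species
#'
#' Each 20 ms window frequency of the trace is treated as an independent
#' sample; the score for species \eqn{s} is the SUM over windows of
#' \eqn{p_s(\mathrm{bin}(f_w))}, the species' probability mass at the
#' window's frequency. Summing (rather than multiplying) prevents a single
#' outlier window with zero mass under a species from vetoing that species
#' outright.
#'
#' @param trace A \code{flight_trace} or numeric vector of window
#'   frequencies (Hz).
#' @param library A \code{\link{reference_library}}.
#' @return Named numeric vector of non-negative scores, one per species,
#'   with attribute \code{all_zero} set when the trace lies entirely
#'   outside every species' support.
#' @export
mle_likelihoods <- function(trace, library) {
  stopifnot(inherits(library, "reference_library"))
  f <- trace_frequencies(trace)
  if (length(f) == 0L) stop("empty trace", call. = FALSE)
  edges <- library$bin_edges
  idx <- findInterval(f, edges, rightmost.closed = FALSE)
  idx[f >= edges[length(edges)]] <- 0L          # out of range on the right
  in_range <- idx >= 1L
  scores <- vapply(library$distributions, function(d) {
    sum(d$prob_mass[idx[in_range]])
  }, numeric(1))
  names(scores) <- library$species
  attr(scores, "all_zero") <- all(scores == 0)
  scores
}

#' Restrict a reference library to species present in a country
#'
#' @param library A \code{\link{reference_library}}.
#' @param matrix A \code{\link{location_matrix}}.
#' @param country ISO-3166 country code (case-insensitive).
#' @return The sub-library of species marked present in \code{country}.
#' @export
filter_by_location <- function(library, matrix, country) {
  stopifnot(inherits(library, "reference_library"),
            inherits(matrix, "location_matrix"))
  country <- toupper(country)
  if (!country %in% colnames(matrix$presence))
    stop("unknown country code: ", country, call. = FALSE)
  missing_rows <- setdiff(library$species, rownames(matrix$presence))
  if (length(missing_rows))
    stop("species absent from location matrix: ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  keep <- library$species[matrix$presence[library$species, country]]
  if (length(keep) == 0L)
    stop("empty candidate set: no library species present in ", country,
         call. = FALSE)
  if (length(keep) == 1L) {
    # a single-species library is degenerate but a valid candidate set here
    out <- library
    out$species <- keep
    out$distributions <- library$distributions[keep]
    return(out)
  }
  out <- reference_library(library$distributions[keep],
                           provenance = library$provenance)
  out$epsilon <- library$epsilon
  out
}

#' Classify a flight trace by maximum likelihood
#'
#' Assigns the trace to the species whose wingbeat frequency distribution
#' is most likely to have produced the observed window frequencies (maximal
#' summed likelihood). When a location matrix and a country are available
#' the candidate set is first restricted to species present in that
#' country. The reported confidence is each score normalized over the
#' post-filter candidates; it is a relative likelihood, not a calibrated
#' probability. Ties are broken lexicographically by species name and
#' flagged.
#'
#' @param trace A \code{flight_trace} or numeric frequency vector.
#' @param library A \code{\link{reference_library}}.
#' @param matrix Optional \code{\link{location_matrix}}.
#' @param meta Optional \code{\link{recording_metadata}} carrying the
#'   recording's country.
#' @param country Optional explicit country code (overrides \code{meta}).
#' @return An object of class \code{classification_result}: list with
#'   \code{predicted_species}, \code{confidence} (named, sums to 1),
#'   \code{scores}, \code{tie}, \code{unclassifiable},
#'   \code{candidates_after_filter}, \code{filter_applied}, \code{country}.
#' @export
classify_trace <- function(trace, library, matrix = NULL, meta = NULL,
                           country = NULL) {
  if (is.null(country) && !is.null(meta) && !is.null(meta$country))
    country <- meta$country
  filter_applied <- FALSE
  if (!is.null(matrix) && !is.null(country)) {
    library <- filter_by_location(library, matrix, country)
    filter_applied <- TRUE
  }
  scores <- mle_likelihoods(trace, library)
  unclassifiable <- isTRUE(attr(scores, "all_zero"))
  conf <- if (unclassifiable) {
    stats::setNames(rep(1 / length(scores), length(scores)), names(scores))
  } else scores / sum(scores)
  best <- which(scores == max(scores))
  tie <- length(best) > 1L
  predicted <- sort(names(scores)[best])[1]
  structure(
    list(predicted_species = predicted, confidence = conf,
         scores = stats::setNames(as.numeric(scores), names(scores)),
         tie = tie, unclassifiable = unclassifiable,
         candidates_after_filter = names(scores),
         filter_applied = filter_applied,
         country = if (is.null(country)) NA_character_ else toupper(country)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s (confidence %.3f%s%s)\n",
              x$predicted_species, x$confidence[x$predicted_species],
              if (x$tie) ", tie" else "",
              if (x$filter_applied) paste0(", filtered to ", x$country) else ""))
  invisible(x)
}

empty_confusion <- function(species) {
  m <- matrix(0, length(species), length(species),
              dimnames = list(predicted = species, true = species))
  m
}

as_confusion <- function(tally, n_trials) {
  cm <- sweep(tally, 2, pmax(1, colSums(tally)), "/")
  structure(list(fractions = cm, trials = colSums(tally),
                 n_trials = n_trials),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d species, diagonal: %s\n",
              nrow(x$fractions),
              paste(sprintf("%.2f", diag(x$fractions)), collapse = " ")))
  invisible(x)
}

#' Bootstrap confusion matrix for a reference library
#'
#' For each species, draws \code{n_trials} random subsets (without
#' replacement) of \code{subset_size} window frequencies from that species'
#' raw data and classifies each subset against the full library; the
#' column-stochastic matrix of classification fractions estimates the
#' intrinsic confusability of the library. Species with essentially
#' non-overlapping distributions classify correctly in > 99% of trials.
#'
#' @param library A \code{\link{reference_library}}.
#' @param raw_frequencies Named list (one element per library species) of
#'   raw per-window frequencies.
#' @param n_trials Bootstrap subsets per species (default 10000).
#' @param subset_size Windows per subset (default 60, about 1.2 s of
#'   recording at the 20 ms stride -- the size at which subset
#'   distributions have converged onto their parents).
#' @param seed RNG seed (optional).
#' @return A \code{confusion_matrix}: \code{fractions} is predicted x true
#'   with columns summing to 1.
#' @export
bootstrap_confusion_matrix <- function(library, raw_frequencies,
                                       n_trials = 10000, subset_size = 60,
                                       seed = NULL) {
  stopifnot(inherits(library, "reference_library"), n_trials >= 1)
  sp <- library$species
  if (!all(sp %in% names(raw_frequencies)))
    stop("raw_frequencies must cover every library species", call. = FALSE)
  n_avail <- vapply(raw_frequencies[sp], length, integer(1))
  if (subset_size > min(n_avail))
    stop("subset_size exceeds the smallest species sample count",
         call. = FALSE)
  mass <- vapply(library$distributions, function(d) d$prob_mass,
                 numeric(length(library$bin_edges) - 1L))
  edges <- library$bin_edges
  with_seed(seed, {
    tally <- empty_confusion(sp)
    for (s in sp) {
      idx_all <- findInterval(raw_frequencies[[s]], edges)
      idx_all[raw_frequencies[[s]] >= edges[length(edges)] |
              raw_frequencies[[s]] < edges[1]] <- 0L
      n <- length(idx_all)
      for (t in seq_len(n_trials)) {
        bins <- idx_all[sample.int(n, subset_size)]
        bins <- bins[bins >= 1L]
        scores <- if (length(bins))
          colSums(mass[bins, , drop = FALSE]) else rep(0, length(sp))
        best <- which(scores == max(scores))
        # ties are broken uniformly at random: a deterministic break would
        # bias the symmetric confusion of equally likely species
        pred <- sp[best[sample.int(length(best), 1L)]]
        tally[pred, s] <- tally[pred, s] + 1
      }
    }
    as_confusion(tally, n_trials)
  })
}

#' K-fold cross-validated confusion matrix
#'
#' Partitions each species' raw window frequencies into K disjoint,
#' exhaustive folds (stratified, so every fold contains every species).
#' Each fold in turn supplies queries -- random subsets of its held-out
#' frequencies -- which are classified against reference distributions
#' rebuilt from the other K-1 folds; results are pooled into one
#' column-stochastic confusion matrix. Unlike the bootstrap, queries are
#' never drawn from the data behind the reference they are scored against.
#'
#' @param raw_frequencies Named list of raw per-window frequencies per
#'   species (>= 2 species, each with at least \code{K} samples).
#' @param K Number of folds, 2--10.
#' @param subset_size Windows per query subset (default 60; capped at the
#'   held-out fold size).
#' @param queries_per_fold Query subsets drawn per species per fold
#'   (default 200).
#' @param bin_width,range Binning for the rebuilt reference distributions.
#' @param seed RNG seed (optional).
#' @return A \code{confusion_matrix}.
#' @export
kfold_validation <- function(raw_frequencies, K, subset_size = 60,
                             queries_per_fold = 200, bin_width = 5,
                             range = c(200, 700), seed = NULL) {
  if (K < 2 || K > 10) stop("K must be between 2 and 10", call. = FALSE)
  sp <- names(raw_frequencies)
  if (length(sp) < 2) stop("need at least two species", call. = FALSE)
  if (any(vapply(raw_frequencies, length, integer(1)) < K))
    stop("every species needs at least K samples", call. = FALSE)
  with_seed(seed, {
    folds <- lapply(raw_frequencies, function(f)
      sample(rep_len(seq_len(K), length(f))))
    tally <- empty_confusion(sp)
    for (k in seq_len(K)) {
      ref <- lapply(sp, function(s)
        build_distribution(raw_frequencies[[s]][folds[[s]] != k],
                           bin_width = bin_width, range = range, label = s))
      names(ref) <- sp
      lib <- reference_library(ref)
      mass <- vapply(lib$distributions, function(d) d$prob_mass,
                     numeric(length(lib$bin_edges) - 1L))
      edges <- lib$bin_edges
      for (s in sp) {
        held <- raw_frequencies[[s]][folds[[s]] == k]
        m <- min(subset_size, length(held))
        idx_all <- findInterval(held, edges)
        idx_all[held >= edges[length(edges)] | held < edges[1]] <- 0L
        for (q in seq_len(queries_per_fold)) {
          bins <- idx_all[sample.int(length(held), m)]
          bins <- bins[bins >= 1L]
          scores <- if (length(bins))
            colSums(mass[bins, , drop = FALSE]) else rep(0, length(sp))
          best <- which(scores == max(scores))
          pred <- sp[best[sample.int(length(best), 1L)]]
          tally[pred, s] <- tally[pred, s] + 1
        }
      }
    }
    as_confusion(tally, K * queries_per_fold)
  })
}

#' Pairwise distance matrix for a reference library
#'
#' Species-by-species matrix with the Jensen-Shannon divergence in the
#' lower triangle and the Bhattacharyya coefficient in the upper triangle;
#' the diagonal is left blank (\code{NA}), as a distribution's distance to
#' itself carries no information.
#'
#' @param library A \code{\link{reference_library}} (>= 2 species).
#' @return A square matrix; attribute \code{n_pairs} gives the number of
#'   unordered species pairs.
#' @export
pairwise_distance_matrix <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  sp <- library$species
  n <- length(sp)
  m <- matrix(NA_real_, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[j, i] <- jensen_shannon_divergence(library$distributions[[i]],
                                           library$distributions[[j]])
      m[i, j] <- bhattacharyya_coefficient(library$distributions[[i]],
                                           library$distributions[[j]])
    }
  }
  attr(m, "n_pairs") <- n * (n - 1) / 2
  m
}

#' Write a confusion matrix to CSV
#'
#' True species as columns (column-stochastic orientation).
#'
#' @param cm A \code{confusion_matrix}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  utils::write.csv(cm$fractions, path)
  invisible(path)
}
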