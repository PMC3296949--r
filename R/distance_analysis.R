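# distance_analysis: all-pairs nitroxide N-N distance distributions
# between two label ensembles, their summaries, histograms, the
# Cbeta-Cbeta reference distance and the +6.5 A rule-of-thumb estimate.
# All conformers weigh equally; the "weighted" mean is the arithmetic
# mean of all pair distances.

#' All-pairs N-N distances between two label ensembles
#'
#' Euclidean distances between the spin-center (nitroxide nitrogen) atoms
#' of every ordered conformer pair (i in `a`, j in `b`), `n_a * n_b`
#' values in total.
#'
#' @param a,b `label_ensemble` objects (non-empty).
#' @return A `distance_set` with `values` (Angstrom), `site_a`, `site_b`,
#'   `n_a`, `n_b` and `subset_label` (`"all"`, or `"snuggly"` when both
#'   inputs are snuggly subsets).
#' @export
pairwise_nn_distances <- function(a, b) {
  stopifnot(inherits(a, "label_ensemble"), inherits(b, "label_ensemble"))
  if (length(a$conformers) == 0L || length(b$conformers) == 0L) {
    stop("label site first: both ensembles must contain conformers")
  }
  pa <- .spin_centers(a)
  pb <- .spin_centers(b)
  d <- sqrt(.dist2_matrix(pa, pb))
  lab_a <- if (identical(a$subset_label, "snuggly")) "snuggly" else "all"
  lab_b <- if (identical(b$subset_label, "snuggly")) "snuggly" else "all"
  structure(list(values = as.numeric(t(d)),
                 site_a = a$site, site_b = b$site,
                 n_a = nrow(pa), n_b = nrow(pb),
                 subset_label = if (lab_a == "snuggly" && lab_b == "snuggly")
                   "snuggly" else "all"),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("N-N distance set (%s): %d x %d = %d values, %.1f-%.1f A\n",
              x$subset_label, x$n_a, x$n_b, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Summary statistics of a distance set
#'
#' Arithmetic mean, median, shortest and longest distance, optionally the
#' Cbeta-Cbeta distance of the two sites, and whether the mean falls into
#' the 15-80 Angstrom PELDOR window.
#'
#' @param d A non-empty `distance_set`.
#' @param s Optional `protein_structure` holding both sites, used for the
#'   Cbeta-Cbeta reference distance.
#' @return A `distance_stats` list: `mean`, `median`, `min`, `max`,
#'   `cb_cb` (`NA` without `s`), `in_peldor_window`.
#' @export
summarize_distances <- function(d, s = NULL) {
  stopifnot(inherits(d, "distance_set"), length(d$values) > 0L)
  v <- d$values
  cb <- if (is.null(s)) NA_real_ else cb_distance(s, d$site_a, d$site_b)
  m <- mean(v)
  structure(list(mean = m, median = stats::median(v),
                 min = min(v), max = max(v), cb_cb = cb,
                 in_peldor_window = m >= 15 && m <= 80),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("mean %.1f A, median %.1f A, range %.1f-%.1f A", x$mean,
              x$median, x$min, x$max))
  if (!is.na(x$cb_cb)) cat(sprintf(", Cb-Cb %.1f A", x$cb_cb))
  cat(sprintf("; mean %s the 15-80 A PELDOR window\n",
              if (x$in_peldor_window) "inside" else "OUTSIDE"))
  invisible(x)
}

#' Histogram of a distance set
#'
#' Half-open bins `[k*w, (k+1)*w)` aligned to multiples of the bin width,
#' covering the full data range; a value exactly on an edge falls into the
#' upper bin.
#'
#' @param d A `distance_set` (or a bare numeric vector of distances).
#' @param bin_width Bin width in Angstrom (> 0), default 1.
#' @param normalize Also store counts scaled to `[0, 1]` (divided by the
#'   modal count), as used for overlaying independently scaled histograms.
#' @return A `distance_histogram` with `bin_edges`, `counts`, `mids`,
#'   optionally `scaled`.
#' @export
distance_histogram <- function(d, bin_width = 1, normalize = FALSE) {
  stopifnot(bin_width > 0)
  v <- if (inherits(d, "distance_set")) d$values else as.numeric(d)
  stopifnot(length(v) > 0L)
  lo <- bin_width * floor(floor(min(v)) / bin_width)
  hi <- bin_width * ceiling(ceiling(max(v)) / bin_width)
  if (hi <= max(v)) hi <- hi + bin_width
  edges <- seq(lo, hi, by = bin_width)
  bin <- findInterval(v, edges)  # edges[i] <= x < edges[i+1]
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 mids = (edges[-1L] + edges[-length(edges)]) / 2,
                 bin_width = bin_width, n = length(v),
                 scaled = if (normalize && max(counts) > 0)
                   counts / max(counts) else NULL),
            class = "distance_histogram")
}

#' Render a distance histogram as text
#'
#' One row per bin with a proportional bar, as printed after a distance
#' calculation.
#'
#' @param h A `distance_histogram`.
#' @param bar_width Width of the longest bar in characters.
#' @return Character vector of lines.
#' @export
format_histogram <- function(h, bar_width = 50L) {
  stopifnot(inherits(h, "distance_histogram"))
  mx <- max(h$counts)
  vapply(seq_along(h$counts), function(i) {
    n_bar <- if (mx == 0L) 0L else round(bar_width * h$counts[i] / mx)
    sprintf("%6.1f - %6.1f A |%-*s %d", h$bin_edges[i], h$bin_edges[i + 1L],
            bar_width, paste(rep("#", n_bar), collapse = ""), h$counts[i])
  }, character(1L))
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(format_histogram(x), sep = "\n")
  invisible(x)
}

#' Most probable (modal) distance of a histogram
#'
#' The center of the modal bin; ties are broken toward the shorter
#' distance so the report is deterministic.
#'
#' @param h A `distance_histogram`.
#' @return Modal distance in Angstrom.
#' @export
modal_distance <- function(h) {
  stopifnot(inherits(h, "distance_histogram"))
  h$mids[which.max(h$counts)]
}

#' Cbeta-Cbeta distance between two sites
#'
#' Glycine sites get an ideal tetrahedral C-beta constructed from their
#' backbone (deterministic across calls).
#'
#' @param s A `protein_structure`.
#' @param a,b `site_ref` objects.
#' @return Distance in Angstrom.
#' @export
cb_distance <- function(s, a, b) {
  cb_of <- function(st) {
    res <- select_residue(s, st)
    .residue_anchor_coords(res, st)["CB", ]
  }
  sqrt(sum((cb_of(a) - cb_of(b))^2))
}

#' Quick rule-of-thumb estimate of the inter-label distance
#'
#' On average the Cbeta-Cbeta distance underestimates the MTSSL N-N
#' distance by about 6.5 Angstrom, so `cb + 6.5` gives a fast first guess
#' of the expected PELDOR distance without any conformer search.
#'
#' @param cb Cbeta-Cbeta distance in Angstrom (>= 0).
#' @return `cb + 6.5` (Angstrom).
#' @export
quick_estimate <- function(cb) {
  stopifnot(all(cb >= 0))
  cb + 6.5
}

#' Circular histograms of the chi angles of an ensemble
#'
#' Counts of each of chi1..chi5 over circular bins partitioning
#' `[0, 360)`; the basis of polar chi-angle plots of an ensemble.
#'
#' @param e A non-empty `label_ensemble`.
#' @param bin_width_deg Bin width in degrees (must divide 360).
#' @return A `chi_histogram`: data.frame with `angle` (chi1..chi5),
#'   `bin_lo`, `bin_hi`, `count`.
#' @export
chi_histogram <- function(e, bin_width_deg = 30) {
  stopifnot(inherits(e, "label_ensemble"), length(e$conformers) > 0L)
  if (360 %% bin_width_deg != 0) stop("bin_width_deg must divide 360")
  chis <- .chi_matrix(e)
  edges <- seq(0, 360, by = bin_width_deg)
  out <- do.call(rbind, lapply(1:5, function(k) {
    cnt <- tabulate(findInterval(chis[, k], edges), nbins = length(edges) - 1L)
    data.frame(angle = paste0("chi", k),
               bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
               count = cnt)
  }))
  class(out) <- c("chi_histogram", "data.frame")
  out
}

#' Polar plot of an ensemble's chi-angle histograms
#'
#' @param x A `chi_histogram`.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.chi_histogram <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 5), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (ang in paste0("chi", 1:5)) {
    sub <- x[x$angle == ang, ]
    mx <- max(sub$count, 1L)
    graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = ang, ...)
    graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                      fg = "grey")
    for (i in seq_len(nrow(sub))) {
      if (sub$count[i] == 0L) next
      th <- .deg2rad(seq(sub$bin_lo[i], sub$bin_hi[i], length.out = 10L))
      r <- sub$count[i] / mx
      graphics::polygon(c(0, r * cos(th)), c(0, r * sin(th)),
                        col = "grey70", border = "grey30")
    }
  }
  invisible(x)
}
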