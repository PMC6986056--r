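# Query, ranking and Craig-plot export over an annotated catalog.
#
# Nearest-neighbour semantics: Euclidean distance in (pi, sigma), by default
# with each axis standardized by the catalog standard deviation so the wide
# pi span (several log units) and the narrow sigma span (about two units)
# weigh equally.  Ties break toward the more frequent (more synthetically
# accessible) substituent, then lexicographically.

#' Query specification for catalog filtering
#'
#' All supplied filters must hold simultaneously; \code{NULL} means "no
#' constraint".
#'
#' @param root_filter character vector of root classes (e.g. \code{"R-O"}).
#' @param attachment_filter character vector of attachment categories (see
#'   \code{\link{attachment_category}}); an entry passes when one of the
#'   named categories reaches \code{attachment_min_share} of its attachment
#'   profile.
#' @param attachment_min_share minimum profile share for
#'   \code{attachment_filter}; the default \code{NULL} requires the named
#'   category to be the entry's modal attachment point.
#' @param max_heavy maximum heavy-atom count.
#' @param min_molecule_freq minimum molecule frequency.
#' @param pi_range,sigma_range closed intervals \code{c(lo, hi)} (use
#'   \code{-Inf}/\code{Inf} for open ends).
#' @param k neighbour count for downstream queries.
#' @return a list of class \code{query_spec}.
#' @export
query_spec <- function(root_filter = NULL, attachment_filter = NULL,
                       attachment_min_share = NULL, max_heavy = NULL,
                       min_molecule_freq = NULL, pi_range = NULL,
                       sigma_range = NULL, k = NULL) {
  chk_range <- function(r, nm) {
    if (!is.null(r) && (length(r) != 2L || r[1] > r[2]))
      stop(nm, " must be c(lo, hi) with lo <= hi")
  }
  chk_range(pi_range, "pi_range")
  chk_range(sigma_range, "sigma_range")
  if (!is.null(k) && k < 1) stop("k must be >= 1")
  structure(list(root_filter = root_filter,
                 attachment_filter = attachment_filter,
                 attachment_min_share = attachment_min_share,
                 max_heavy = max_heavy,
                 min_molecule_freq = min_molecule_freq,
                 pi_range = pi_range, sigma_range = sigma_range, k = k),
            class = "query_spec")
}

#' Filter a catalog by a query specification
#'
#' @param catalog annotated \code{substituent_catalog}.
#' @param query a \code{query_spec} (or plain list with the same fields).
#' @return the matching sub-catalog (possibly empty); applying the same
#'   query twice is idempotent.
#' @export
filter_catalog <- function(catalog, query) {
  keep <- rep(TRUE, nrow(catalog))
  q <- query
  if (!is.null(q$root_filter))
    keep <- keep & catalog$root_class %in% q$root_filter
  if (!is.null(q$max_heavy))
    keep <- keep & catalog$heavy_atoms <= q$max_heavy
  if (!is.null(q$min_molecule_freq))
    keep <- keep & catalog$molecule_frequency >= q$min_molecule_freq
  if (!is.null(q$pi_range))
    keep <- keep & !is.na(catalog$pi) & catalog$pi >= q$pi_range[1] &
      catalog$pi <= q$pi_range[2]
  if (!is.null(q$sigma_range))
    keep <- keep & !is.na(catalog$sigma) & catalog$sigma >= q$sigma_range[1] &
      catalog$sigma <= q$sigma_range[2]
  if (!is.null(q$attachment_filter)) {
    cols <- .ATT_COLS[match(q$attachment_filter, .ATT_LEVELS)]
    if (anyNA(cols))
      stop("unknown attachment categor(ies): ",
           paste(q$attachment_filter[is.na(cols)], collapse = ", "))
    prof <- as.matrix(catalog[, .ATT_COLS, drop = FALSE])
    tot <- pmax(rowSums(prof), 1)
    share <- rowSums(prof[, cols, drop = FALSE]) / tot
    if (is.null(q$attachment_min_share)) {
      modal <- .ATT_COLS[max.col(prof, ties.method = "first")]
      keep <- keep & modal %in% cols
    } else {
      keep <- keep & share >= q$attachment_min_share
    }
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("corpus_size", "min_molecule_freq"))
    attr(out, a) <- attr(catalog, a)
  class(out) <- class(catalog)
  out
}

.property_matrix <- function(catalog, scaling) {
  m <- cbind(pi = catalog$pi, sigma = catalog$sigma)
  scale_by <- c(pi = 1, sigma = 1)
  if (scaling == "standardize") {
    sds <- apply(m, 2, stats::sd, na.rm = TRUE)
    sds[!is.finite(sds) | sds == 0] <- 1
    scale_by <- sds
  }
  list(m = sweep(m, 2, scale_by, "/"), scale_by = scale_by)
}

#' Nearest bioisosteric neighbours in (pi, sigma) space
#'
#' Substituents close together on the Craig plot are expected to act as
#' mutual bioisosteres.  Distances are Euclidean in (optionally per-axis
#' standardized) property space.
#'
#' @param catalog annotated \code{substituent_catalog}.
#' @param target attachment-marked SMILES, or a list/row with \code{pi} and
#'   \code{sigma}; properties of a SMILES target are computed on the fly
#'   when it is not in the catalog.
#' @param k number of neighbours (capped at the catalog size with a
#'   warning).
#' @param scaling \code{"standardize"} (default) or \code{"raw"}.
#' @param include_self keep the target itself (matched by canonical SMILES)
#'   in the ranking; default \code{FALSE}.
#' @param calibration used when the target's sigma must be computed.
#' @return the k nearest entries with a \code{distance} column, distances
#'   non-decreasing; ties broken by higher molecule frequency, then SMILES.
#' @export
nearest_bioisosteres <- function(catalog, target, k = 5L,
                                 scaling = c("standardize", "raw"),
                                 include_self = FALSE,
                                 calibration = NULL) {
  scaling <- match.arg(scaling)
  cat_ok <- catalog[!is.na(catalog$pi) & !is.na(catalog$sigma), ,
                    drop = FALSE]
  target_smiles <- NULL
  if (is.character(target)) {
    target_smiles <- canonical_substituent(target)$smiles
    hit <- match(target_smiles, cat_ok$smiles)
    if (!is.na(hit)) {
      tv <- c(cat_ok$pi[hit], cat_ok$sigma[hit])
    } else {
      if (is.null(calibration)) calibration <- default_calibration()
      tv <- c(compute_pi(target_smiles),
              compute_sigma(target_smiles, calibration))
    }
  } else {
    tv <- c(target$pi, target$sigma)
  }
  if (anyNA(tv)) stop("target has no finite (pi, sigma)")
  if (!include_self && !is.null(target_smiles))
    cat_ok <- cat_ok[cat_ok$smiles != target_smiles, , drop = FALSE]
  if (k > nrow(cat_ok)) {
    warning("k exceeds catalog size; returning all ", nrow(cat_ok),
            " entries")
    k <- nrow(cat_ok)
  }
  pm <- .property_matrix(cat_ok, scaling)
  tz <- tv / pm$scale_by
  d <- sqrt((pm$m[, 1] - tz[1])^2 + (pm$m[, 2] - tz[2])^2)
  ord <- order(d, -cat_ok$molecule_frequency, cat_ok$smiles)
  out <- cat_ok[ord[seq_len(k)], , drop = FALSE]
  out$distance <- d[ord[seq_len(k)]]
  rownames(out) <- NULL
  out
}

#' Craig-plot quadrant of a property vector
#'
#' @param pi,sigma numeric scalars (or a length-2 vector given as \code{pi}).
#' @return one of \code{"pi+sigma+"}, \code{"pi+sigma-"},
#'   \code{"pi-sigma+"}, \code{"pi-sigma-"}, or \code{"boundary"} when
#'   either coordinate is exactly zero.
#' @export
quadrant_of <- function(pi, sigma = NULL) {
  if (is.null(sigma)) { sigma <- pi[2]; pi <- pi[1] }
  stopifnot(is.finite(pi), is.finite(sigma))
  if (pi == 0 || sigma == 0) return("boundary")
  paste0("pi", if (pi > 0) "+" else "-",
         "sigma", if (sigma > 0) "+" else "-")
}

#' Diverse (max-min) selection in property space
#'
#' Picks \code{n} substituents maximizing the minimum pairwise distance in
#' standardized (pi, sigma).  Small problems (at most 500 candidate subsets)
#' are solved exactly by enumeration, with ties broken toward the more
#' frequent selection; larger ones use the classic greedy farthest-point
#' heuristic seeded at the most frequent substituent.  When all four Craig
#' quadrants are populated the first four picks cover at least three of
#' them.
#'
#' @param catalog annotated \code{substituent_catalog}.
#' @param n number of entries to select; the whole catalog when \code{n}
#'   exceeds its size.
#' @return the selected sub-catalog, in pick order.
#' @export
diverse_selection <- function(catalog, n) {
  cat_ok <- catalog[!is.na(catalog$pi) & !is.na(catalog$sigma), ,
                    drop = FALSE]
  N <- nrow(cat_ok)
  if (n >= N) return(cat_ok)
  pm <- .property_matrix(cat_ok, "standardize")$m
  if (n >= 2 && choose(N, n) <= 500) {
    dm <- as.matrix(stats::dist(pm))
    combos <- utils::combn(N, n)
    score <- apply(combos, 2, function(ix) min(dm[ix, ix][upper.tri(
      matrix(0, n, n))]))
    best <- which(score >= max(score) - 1e-12)
    if (length(best) > 1) {
      freq <- apply(combos[, best, drop = FALSE], 2,
                    function(ix) sum(cat_ok$molecule_frequency[ix]))
      best <- best[order(-freq)[1]]
    }
    picked <- combos[, best[1]]
  } else {
    seed <- order(-cat_ok$molecule_frequency, cat_ok$smiles)[1]
    picked <- seed
    mind <- sqrt(rowSums(sweep(pm, 2, pm[seed, ])^2))
    while (length(picked) < n) {
      cand <- which.max(replace(mind, picked, -Inf))
      picked <- c(picked, cand)
      d_new <- sqrt(rowSums(sweep(pm, 2, pm[cand, ])^2))
      mind <- pmin(mind, d_new)
    }
  }
  out <- cat_ok[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Craig-plot data from an annotated catalog
#'
#' @param catalog annotated \code{substituent_catalog}.
#' @return data frame of class \code{craig_plot_data}: label, pi, sigma,
#'   molecule frequency, a monotone point-size encoding of frequency, and
#'   the quadrant.
#' @export
craig_plot_data <- function(catalog) {
  cat_ok <- catalog[!is.na(catalog$pi) & !is.na(catalog$sigma), ,
                    drop = FALSE]
  if (!nrow(cat_ok)) stop("no annotated entries to plot")
  size <- 1 + 2 * log10(pmax(cat_ok$molecule_frequency, 1))
  out <- data.frame(label = cat_ok$smiles, pi = cat_ok$pi,
                    sigma = cat_ok$sigma,
                    molecule_frequency = cat_ok$molecule_frequency,
                    size = size,
                    quadrant = mapply(quadrant_of, cat_ok$pi, cat_ok$sigma))
  rownames(out) <- NULL
  class(out) <- c("craig_plot_data", "data.frame")
  out
}

#' Render a Craig plot
#'
#' Writes a static scatter of sigma against pi with origin cross-hairs and
#' frequency-scaled points, plus a machine-readable sidecar TSV of the
#' plotted points (same path with extension \code{.tsv}).
#'
#' @param data a \code{craig_plot_data} (or an annotated catalog, converted
#'   on the fly).
#' @param path output figure path; the device is chosen from the extension
#'   (\code{.png} or \code{.pdf}).
#' @param labels draw substituent labels next to the points.
#' @param width,height device size in inches.
#' @return invisibly, a list with the figure path and sidecar path.
#' @export
render_craig_plot <- function(data, path, labels = FALSE,
                              width = 7, height = 6) {
  if (inherits(data, "substituent_catalog")) data <- craig_plot_data(data)
  if (!nrow(data)) stop("empty plot data")
  xr <- range(data$pi)
  yr <- range(data$sigma)
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- 1
    r + c(-1, 1) * 0.05 * w
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = pi, y = sigma)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = size), alpha = 0.7,
                        colour = "#2166ac", show.legend = FALSE) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_cartesian(xlim = pad(xr), ylim = pad(yr)) +
    ggplot2::labs(x = expression(pi ~ "(hydrophobicity)"),
                  y = expression(sigma ~ "(electronic)"),
                  title = "Craig plot") +
    ggplot2::theme_minimal()
  if (labels)
    p <- p + ggplot2::geom_text(ggplot2::aes(label = label),
                                size = 2.5, vjust = -1)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  sidecar <- paste0(sub("\\.[A-Za-z]+$", "", path), ".tsv")
  utils::write.table(as.data.frame(data), sidecar, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(figure = path, sidecar = sidecar))
}
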