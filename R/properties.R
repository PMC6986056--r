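# Substituent properties: Hansch-Fujita pi and a Hammett sigma-para
# compatible electronic parameter.
#
# pi is the atom-contribution (Wildman-Crippen) logP of the mono-substituted
# benzene probe minus the logP of benzene, so pi(H) = 0 by construction.
# The electronic descriptor is the change, relative to benzene, of the
# total (PEOE sigma + Huckel pi) charge on the ring carbon para to the
# substituent plus its hydrogen; a linear calibration against experimental
# sigma-para values maps the descriptor onto the Hammett scale.

#' Atom-contribution logP
#'
#' Octanol-water logP by the Wildman-Crippen atom-contribution scheme, as
#' implemented in Open Babel.  Deterministic and permutation-invariant.
#'
#' @param molecule SMILES string(s) or a \code{molgraph}.
#' @return numeric vector of logP values.
#' @export
logp_atom_contrib <- function(molecule) {
  if (inherits(molecule, "molgraph")) molecule <- write_smiles(molecule)
  out <- rep(NA_real_, length(molecule))
  src <- paste0(molecule, " i", seq_along(molecule), collapse = "\n")
  res <- ChemmineOB::forEachMol("SMILES", paste0(src, "\n"),
                                function(m) ChemmineOB::prop_OB(m))
  if (length(res) != length(molecule)) {
    for (k in seq_along(molecule)) {
      r <- tryCatch(ChemmineOB::forEachMol(
        "SMILES", paste0(molecule[k], " x\n"),
        function(m) ChemmineOB::prop_OB(m)), error = function(e) NULL)
      if (length(r)) out[k] <- r[[1]]$logP
    }
    return(out)
  }
  for (k in seq_along(res)) {
    id <- as.integer(sub("^i", "", res[[k]]$title))
    out[id] <- res[[k]]$logP
  }
  out
}

#' Build the substituted-benzene probe of a substituent
#'
#' Replaces the attachment wildcard by a bond to a benzene ring carbon.  The
#' hydrogen substituent \code{"[*][H]"} gives benzene itself.
#'
#' @param substituent attachment-marked SMILES or \code{molgraph}.
#' @return a \code{molgraph} with attributes \code{ipso} and \code{para}
#'   (indices of the substituted ring carbon and the carbon para to it) and
#'   \code{smiles} (a writable SMILES of the probe).
#' @export
build_probe <- function(substituent) {
  smi <- if (inherits(substituent, "molgraph")) NULL else substituent
  if (!is.null(smi) && gsub("\\[\\*\\]|\\*", "", smi) %in%
        c("[H]", "")) {
    g <- parse_smiles("c1ccccc1")
    attr(g, "ipso") <- 1L
    attr(g, "para") <- 4L
    attr(g, "smiles") <- "c1ccccc1"
    return(g)
  }
  f <- if (inherits(substituent, "molgraph")) substituent else
    parse_smiles(substituent)
  star <- which(f$atoms$element == "*")
  if (length(star) != 1L)
    stop("substituent must carry exactly one attachment point")
  nb <- atom_neighbours(f, star)
  if (nrow(nb) != 1L || nb$order != 1L)
    stop("attachment point must have exactly one single bond")
  root <- nb$atom
  # the root atom must be able to bond to an aromatic carbon: it already
  # spends one valence unit on the wildcard, which the ring bond replaces
  keep <- setdiff(seq_len(n_atoms(f)), star)
  sub <- subgraph(f, keep)
  root_local <- match(root, keep)
  n0 <- n_atoms(sub)
  ring_atoms <- data.frame(element = rep("C", 6), charge = 0L,
                           aromatic = TRUE, ring = TRUE,
                           nH = c(0L, 1L, 1L, 1L, 1L, 1L))
  sub$atoms <- rbind(sub$atoms, ring_atoms)
  ring_idx <- n0 + 1:6
  kek <- c(2L, 1L, 2L, 1L, 2L, 1L)
  rb <- data.frame(a1 = ring_idx, a2 = ring_idx[c(2:6, 1)], order = kek,
                   aromatic = TRUE, ring = TRUE)
  ab <- data.frame(a1 = root_local, a2 = ring_idx[1], order = 1L,
                   aromatic = FALSE, ring = FALSE)
  sub$bonds <- rbind(sub$bonds, rb, ab)
  rownames(sub$atoms) <- NULL
  rownames(sub$bonds) <- NULL
  sub$atoms$nH <- .implicit_h(sub)
  probe_smiles <- write_smiles(sub, root = ring_idx[1])
  if (is.na(canonical_smiles(probe_smiles)))
    stop("substituent cannot be attached to an aromatic carbon: ",
         if (is.null(smi)) "<graph>" else smi)
  attr(sub, "ipso") <- ring_idx[1]
  attr(sub, "para") <- ring_idx[4]
  attr(sub, "smiles") <- probe_smiles
  sub
}

#' Hansch-Fujita pi of substituents
#'
#' \code{pi = logP(probe) - logP(benzene)}, both by atom contributions, so
#' the hydrogen substituent has pi exactly 0.
#'
#' @param substituent character vector of attachment-marked SMILES.
#' @return numeric vector; \code{NA} where no probe can be built.
#' @export
compute_pi <- function(substituent) {
  probes <- vapply(substituent, function(s) {
    tryCatch(attr(build_probe(s), "smiles"), error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
  out <- rep(NA_real_, length(substituent))
  ok <- !is.na(probes)
  if (any(ok)) {
    lp <- logp_atom_contrib(c("c1ccccc1", probes[ok]))
    out[ok] <- lp[-1] - lp[1]
  }
  out
}

#' Electronic charge descriptor of a probe
#'
#' The sum of the total (PEOE sigma + Huckel pi) charge on the ring carbon
#' para to the substituent and the sigma charge of its hydrogen, minus the
#' same sum computed on benzene.  Electron-withdrawing substituents give a
#' positive descriptor, donors a negative one.
#'
#' @param probe a probe \code{molgraph} from \code{\link{build_probe}}, or an
#'   attachment-marked substituent SMILES (the probe is then built first).
#' @param max_iter,tol forwarded to \code{\link{peoe_charges}}.
#' @return a single numeric value.
#' @export
charge_descriptor <- function(probe, max_iter = 200L, tol = 1e-6) {
  if (!inherits(probe, "molgraph")) probe <- build_probe(probe)
  para <- attr(probe, "para")
  if (is.null(para))
    stop("probe must carry a 'para' attribute (use build_probe)")
  .para_sum(probe, para, max_iter, tol) -
    .benzene_reference(max_iter, tol)
}

.para_sum <- function(g, para, max_iter, tol) {
  qs <- peoe_charges(g, max_iter = max_iter, tol = tol)
  qp <- huckel_pi_charges(g, sigma_charges = qs$q_heavy)
  nH_para <- g$atoms$nH[para]
  qh <- if (nH_para > 0) qs$q_h[para] / nH_para else 0
  qs$q_heavy[para] + qp[para] + qh
}

.descriptor_cache <- new.env(parent = emptyenv())

.benzene_reference <- function(max_iter, tol) {
  key <- paste0("benzene_", max_iter, "_", tol)
  if (!is.null(.descriptor_cache[[key]])) return(.descriptor_cache[[key]])
  g <- parse_smiles("c1ccccc1")
  val <- .para_sum(g, 4L, max_iter, tol)
  .descriptor_cache[[key]] <- val
  val
}

#' Fit the linear calibration from charge descriptor to the sigma scale
#'
#' Ordinary least squares of experimental sigma-para values on the charge
#' descriptor.  The calibration bridges the in-silico descriptor to the
#' experimental Hammett scale.
#'
#' @param training_pairs data frame with columns \code{descriptor} and
#'   \code{sigma_exp}, or with \code{smiles} and \code{sigma_exp} (the
#'   descriptors are then computed).
#' @return an object of class \code{sigma_calibration}: slope, intercept,
#'   r_squared, n_train, and the standard errors of the coefficients.
#' @export
fit_sigma_calibration <- function(training_pairs) {
  tp <- as.data.frame(training_pairs)
  if (!"descriptor" %in% names(tp)) {
    if (!"smiles" %in% names(tp))
      stop("training_pairs needs a 'descriptor' or 'smiles' column")
    tp$descriptor <- vapply(tp$smiles, function(s)
      charge_descriptor(build_probe(s)), 0, USE.NAMES = FALSE)
  }
  if (!"sigma_exp" %in% names(tp))
    stop("training_pairs needs a 'sigma_exp' column")
  tp <- tp[is.finite(tp$descriptor) & is.finite(tp$sigma_exp), , drop = FALSE]
  if (nrow(tp) < 2) stop("at least 2 training pairs are required")
  if (diff(range(tp$descriptor)) < .Machine$double.eps^0.5)
    stop("degenerate fit: all descriptors are identical")
  fit <- stats::lm(sigma_exp ~ descriptor, data = tp)
  # summary.lm warns on exact fits; the exact case is legitimate here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = sm$coefficients[2, 2],
    intercept_se = sm$coefficients[1, 2],
    r_squared = sm$r.squared,
    n_train = nrow(tp)
  ), class = "sigma_calibration")
}

#' @export
print.sigma_calibration <- function(x, ...) {
  cat(sprintf(
    "sigma calibration: sigma = %.4g * descriptor + %.4g  (r^2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_train))
  invisible(x)
}

#' Hammett-compatible sigma of substituents
#'
#' Applies a fitted calibration to the charge descriptor of each
#' substituent's benzene probe.
#'
#' @param substituent character vector of attachment-marked SMILES.
#' @param model a \code{sigma_calibration}.
#' @return numeric vector; \code{NA} where no probe can be built.
#' @export
compute_sigma <- function(substituent, model) {
  stopifnot(inherits(model, "sigma_calibration"))
  vapply(substituent, function(s) {
    d <- tryCatch(charge_descriptor(s), error = function(e) NA_real_)
    model$slope * d + model$intercept
  }, 0, USE.NAMES = FALSE)
}

#' Evaluate a sigma calibration on reference pairs
#'
#' @param model a \code{sigma_calibration}.
#' @param reference_pairs data frame with \code{descriptor} (or
#'   \code{smiles}) and \code{sigma_exp} columns.
#' @return list with \code{r_squared}, \code{mae} and \code{n}.
#' @export
evaluate_calibration <- function(model, reference_pairs) {
  rp <- as.data.frame(reference_pairs)
  if (!"descriptor" %in% names(rp)) {
    if (!"smiles" %in% names(rp))
      stop("reference_pairs needs a 'descriptor' or 'smiles' column")
    rp$descriptor <- vapply(rp$smiles, function(s)
      charge_descriptor(build_probe(s)), 0, USE.NAMES = FALSE)
  }
  rp <- rp[is.finite(rp$descriptor) & is.finite(rp$sigma_exp), , drop = FALSE]
  if (nrow(rp) < 2) stop("at least 2 reference pairs are required")
  pred <- model$slope * rp$descriptor + model$intercept
  ss_res <- sum((rp$sigma_exp - pred)^2)
  ss_tot <- sum((rp$sigma_exp - mean(rp$sigma_exp))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       mae = mean(abs(rp$sigma_exp - pred)),
       n = nrow(rp))
}

#' Default sigma calibration from the packaged experimental table
#'
#' Fits the descriptor-to-sigma calibration on the experimental sigma-para
#' compilation shipped with the package (classic mono-substituted benzene
#' constants transcribed from the common literature tables).
#'
#' @return a \code{sigma_calibration} (cached within the session).
#' @export
default_calibration <- function() {
  if (!is.null(.descriptor_cache$default_calibration))
    return(.descriptor_cache$default_calibration)
  path <- system.file("extdata", "sigma_para_literature.tsv",
                      package = "substispace", mustWork = TRUE)
  model <- fit_sigma_calibration(read_constant_table(path))
  .descriptor_cache$default_calibration <- model
  model
}

#' Read a substituent-constant table
#'
#' Tab-separated with a header and \code{#} comment lines at the top.  Only
#' whole lines starting with \code{#} are treated as comments: SMILES strings
#' legitimately contain \code{#} (triple bonds), so no in-line comment
#' stripping is applied.
#'
#' @param path file path.
#' @return data frame with the file's columns (at least \code{smiles} and
#'   \code{sigma_exp}).
#' @export
read_constant_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                    comment.char = "", quote = "")
}

#' Annotate a catalog with pi and sigma
#'
#' Computes both properties for every catalog entry.  Entries whose probe
#' cannot be built (attachment valence problems) keep \code{NA} and are
#' counted in a warning.
#'
#' @param catalog a \code{substituent_catalog}.
#' @param calibration a \code{sigma_calibration}; defaults to the packaged
#'   literature calibration.
#' @return the catalog with \code{pi} and \code{sigma} filled in.
#' @export
annotate_catalog <- function(catalog, calibration = default_calibration()) {
  if (!nrow(catalog)) return(catalog)
  catalog$pi <- compute_pi(catalog$smiles)
  catalog$sigma <- compute_sigma(catalog$smiles, calibration)
  n_bad <- sum(is.na(catalog$pi) | is.na(catalog$sigma))
  if (n_bad)
    warning(n_bad, " substituent(s) could not be annotated (probe failure)")
  catalog
}
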