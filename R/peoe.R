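# Sigma-framework partial charges by partial equalization of orbital
# electronegativity (PEOE).  Orbital electronegativity is the quadratic
# chi(q) = a + b q + c q^2 with published coefficients per element and
# hybridization; on each sweep every bond transfers charge proportional to
# the electronegativity difference, damped by 2^-n, so the iteration is
# strictly convergent and deterministic.

# a, b, c by orbital type
.PEOE_PARAMS <- rbind(
  H     = c(7.17,  6.24, -0.56),
  C.3   = c(7.98,  9.18,  1.88),
  C.2   = c(8.79,  9.32,  1.51),
  C.1   = c(10.39, 9.45,  0.73),
  N.3   = c(11.54, 10.82, 1.36),
  N.2   = c(12.87, 11.15, 0.85),
  N.1   = c(15.68, 11.70, -0.27),
  O.3   = c(14.18, 12.92, 1.39),
  O.2   = c(17.07, 13.79, 0.47),
  F     = c(14.66, 13.85, 2.31),
  Cl    = c(11.00, 9.69,  1.35),
  Br    = c(10.08, 8.47,  1.16),
  I     = c(9.90,  7.96,  0.96),
  S.3   = c(10.14, 9.13,  1.38),
  P.3   = c(8.90,  8.24,  0.96),
  B.3   = c(5.98,  6.82,  1.60)
)

# hybridization label: .1 (sp), .2 (sp2 / aromatic), .3 (sp3)
.hybridization <- function(g) {
  n <- n_atoms(g)
  hyb <- rep("3", n)
  if (nrow(g$bonds)) {
    for (i in seq_len(n)) {
      nb <- atom_neighbours(g, i)
      if (!nrow(nb)) next
      ndouble <- sum(nb$order == 2 & !nb$aromatic)
      ntriple <- sum(nb$order == 3)
      if (ntriple >= 1L || ndouble >= 2L) hyb[i] <- "1"
      else if (ndouble >= 1L || g$atoms$aromatic[i] || any(nb$aromatic))
        hyb[i] <- "2"
    }
  }
  hyb
}

.peoe_type <- function(element, hyb) {
  if (element %in% c("H", "F", "Cl", "Br", "I")) return(element)
  if (element %in% c("S", "P", "B")) return(paste0(element, ".3"))
  t <- paste0(element, ".", hyb)
  if (t %in% rownames(.PEOE_PARAMS)) t else NA_character_
}

#' Sigma partial charges by iterative electronegativity equalization
#'
#' Computes PEOE (Gasteiger-Marsili type) sigma charges on the hydrogen-
#' expanded molecular graph.  Formal charges seed the iteration.  Atoms whose
#' element or hybridization has no tabulated coefficients keep their seed
#' charge and do not exchange charge (a warning is issued).
#'
#' @param g a \code{molgraph} (no wildcard atoms).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on the largest per-sweep charge move
#'   (default 1e-6).
#' @return a list: \code{q_heavy} charges of the graph's atoms,
#'   \code{q_h} summed charges of each atom's implicit hydrogens,
#'   \code{iterations} sweeps used.
#' @export
peoe_charges <- function(g, max_iter = 200L, tol = 1e-6) {
  if (any(g$atoms$element == "*"))
    stop("peoe_charges requires a fully specified molecule (no wildcard)")
  nh <- n_atoms(g)
  hyb <- .hybridization(g)
  # expand implicit hydrogens into explicit atoms
  n_ext <- nh + sum(g$atoms$nH)
  element <- c(g$atoms$element, rep("H", n_ext - nh))
  parent <- c(seq_len(nh), rep(NA_integer_, n_ext - nh))
  b1 <- g$bonds$a1
  b2 <- g$bonds$a2
  k <- nh
  for (i in seq_len(nh)) {
    if (g$atoms$nH[i] > 0) {
      for (j in seq_len(g$atoms$nH[i])) {
        k <- k + 1L
        parent[k] <- i
        b1 <- c(b1, i)
        b2 <- c(b2, k)
      }
    }
  }
  type <- character(n_ext)
  for (i in seq_len(n_ext))
    type[i] <- .peoe_type(element[i], if (i <= nh) hyb[i] else "")
  known <- !is.na(type)
  if (any(!known))
    warning("no PEOE coefficients for element(s): ",
            paste(unique(element[!known]), collapse = ", "),
            "; treated as inert")
  a <- b <- cc <- rep(NA_real_, n_ext)
  a[known] <- .PEOE_PARAMS[type[known], 1]
  b[known] <- .PEOE_PARAMS[type[known], 2]
  cc[known] <- .PEOE_PARAMS[type[known], 3]
  chi_plus <- a + b + cc           # cation electronegativity
  chi_plus[known & element == "H"] <- 20.02
  q <- c(as.numeric(g$atoms$charge), rep(0, n_ext - nh))
  damp <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    damp <- damp * 0.5
    chi <- a + b * q + cc * q * q
    dq <- rep(0, n_ext)
    for (e in seq_along(b1)) {
      i <- b1[e]; j <- b2[e]
      if (!known[i] || !known[j]) next
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (chi[i] < chi[j]) j else i
      move <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      dq[lo] <- dq[lo] + move
      dq[hi] <- dq[hi] - move
    }
    q <- q + dq
    if (max(abs(dq)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("PEOE charge iteration did not converge in ", max_iter,
         " sweeps (last max |dq| = ", format(max(abs(dq))), ")")
  q_h <- vapply(seq_len(nh), function(i)
    sum(q[which(parent == i & seq_len(n_ext) > nh)]), 0)
  list(q_heavy = q[seq_len(nh)], q_h = q_h, iterations = iter)
}
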