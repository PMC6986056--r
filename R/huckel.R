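# Pi-electron charges from simple Huckel molecular-orbital theory with
# standard heteroatom parameters.  The sigma charge model (PEOE) cannot
# express resonance donation -- a dimethylamino nitrogen is more
# electronegative than carbon yet pushes pi density onto the ring -- so the
# electronic descriptor combines PEOE sigma charges with Huckel pi charges,
# the classic two-part treatment of substituted benzenes.
#
# Coulomb integrals are written alpha + h*beta and resonance integrals
# k*beta, with h and k from the standard organic-chemistry compilations.
# One-electron centres are multiply bonded (or pyridine-type aromatic)
# atoms; two-electron centres are conjugated lone-pair donors, including
# pyrrole-type ring heteroatoms.  Saturated carbons attached to the pi
# system enter as two-electron hyperconjugative pseudo-centres (the
# heteroatom model of the methyl group).  A formal charge shifts h by +1
# per unit charge.  Induction enters through the omega technique: every
# centre's Coulomb integral is shifted by omega times its PEOE sigma
# charge, so e.g. the pseudo-methyl orbital of a CF3 carbon is pulled far
# below that of a plain methyl and stops donating.

# h parameters: one-electron ("pi") and two-electron ("lp") values
.HUCKEL_H <- list(
  C  = c(pi = 0.0, lp = NA),
  N  = c(pi = 0.5, lp = 1.5),
  O  = c(pi = 1.0, lp = 2.0),
  S  = c(pi = 0.5, lp = 1.3),
  P  = c(pi = 0.3, lp = 0.8),
  F  = c(pi = NA,  lp = 3.0),
  Cl = c(pi = NA,  lp = 2.0),
  Br = c(pi = NA,  lp = 2.0),
  I  = c(pi = NA,  lp = 2.0),
  Me = c(pi = NA,  lp = 3.0)   # hyperconjugative sp3 carbon
)

.k_key <- function(lab1, lab2) paste(sort(c(lab1, lab2)), collapse = "-")

.HUCKEL_K <- local({
  pairs <- list(
    list("C.pi", "C.pi", 1.0), list("C.pi", "Me.lp", 0.7),
    list("C.pi", "N.pi", 1.0), list("C.pi", "N.lp", 0.8),
    list("C.pi", "O.pi", 1.0), list("C.pi", "O.lp", 0.8),
    list("C.pi", "S.pi", 0.8), list("C.pi", "S.lp", 0.6),
    list("C.pi", "F.lp", 0.7), list("C.pi", "Cl.lp", 0.4),
    list("C.pi", "Br.lp", 0.3), list("C.pi", "I.lp", 0.25),
    list("N.pi", "O.pi", 0.7), list("N.pi", "O.lp", 0.7),
    list("N.pi", "N.pi", 0.8), list("N.pi", "N.lp", 0.8),
    list("N.lp", "O.pi", 0.7), list("S.pi", "O.pi", 0.6)
  )
  setNames(vapply(pairs, `[[`, 0, 3L),
           vapply(pairs, function(p) .k_key(p[[1]], p[[2]]), ""))
})

.huckel_k <- function(lab1, lab2) {
  key <- .k_key(lab1, lab2)
  if (!is.na(.HUCKEL_K[key])) unname(.HUCKEL_K[key]) else 0.7
}

# Characterize the conjugated system.  Returns per-atom:
#   member  -- belongs to the pi system
#   core    -- aromatic or multiply bonded (as opposed to attached donor)
#   elem    -- element label ("Me" for hyperconjugative carbons)
#   nelec   -- pi electrons contributed (1 or 2)
#   role    -- "pi" (1 electron) or "lp" (2 electrons)
.pi_system <- function(g) {
  n <- n_atoms(g)
  core <- logical(n)
  for (i in seq_len(n)) {
    nb <- atom_neighbours(g, i)
    if (!nrow(nb)) next
    if (g$atoms$aromatic[i] || any(nb$order >= 2 & !nb$aromatic))
      core[i] <- TRUE
  }
  member <- core
  elem <- g$atoms$element
  nelec <- rep(0L, n)
  for (i in which(core)) {
    el <- elem[i]
    nb <- atom_neighbours(g, i)
    if (g$atoms$aromatic[i] && el %in% c("N", "O", "S", "P") &&
        !any(nb$order == 2)) {
      nelec[i] <- 2L           # pyrrole/furan/thiophene-type ring donor
    } else {
      nelec[i] <- 1L
    }
  }
  # attached donors: lone-pair heteroatoms and hyperconjugative carbons
  for (i in which(!core)) {
    el <- elem[i]
    nb <- atom_neighbours(g, i)
    if (!nrow(nb) || !any(core[nb$atom])) next
    ch <- g$atoms$charge[i]
    if (el %in% c("N", "O", "S", "P") && ch <= 0) {
      # needs an available lone pair: positive centres are excluded above,
      # four-coordinate neutral N (etc.) has none either
      if (nrow(nb) + g$atoms$nH[i] <= STANDARD_VALENCE[[el]] - ch) {
        member[i] <- TRUE
        nelec[i] <- 2L
      }
    } else if (el %in% HALOGENS && ch == 0) {
      member[i] <- TRUE
      nelec[i] <- 2L
    } else if (el == "C" && ch == 0) {
      member[i] <- TRUE
      nelec[i] <- 2L
      elem[i] <- "Me"
    }
  }
  role <- ifelse(nelec == 2L, "lp", "pi")
  role[!member] <- NA_character_
  list(member = member, core = core, elem = elem, nelec = nelec, role = role)
}

.huckel_h_value <- function(g, sys, i, omega = 0, q_sigma = NULL) {
  base <- .HUCKEL_H[[sys$elem[i]]]
  if (is.null(base)) base <- c(pi = 0.5, lp = 1.0)
  h <- unname(base[[sys$role[i]]])
  if (is.na(h)) h <- unname(base[[if (sys$role[i] == "pi") "lp" else "pi"]])
  h <- h + g$atoms$charge[i]  # formal charge raises/lowers the Coulomb term
  if (omega != 0 && !is.null(q_sigma)) h <- h + omega * q_sigma[i]
  h
}

#' Pi charges from a simple Huckel treatment
#'
#' Builds the conjugated system of the molecule, solves the Huckel secular
#' problem with standard heteroatom h/k parameters, and returns the pi charge
#' (electrons contributed minus pi population) per atom; atoms outside the
#' conjugated system have pi charge 0.  Degenerate frontier orbitals are
#' occupied evenly, so closed- and open-shell fillings are both deterministic.
#'
#' @param g a \code{molgraph}.
#' @param omega strength of the sigma-to-pi inductive coupling (default 1.4,
#'   the customary omega-technique value); 0 disables it.
#' @param sigma_charges per-atom sigma charges for the coupling; computed
#'   with \code{\link{peoe_charges}} when omitted and \code{omega != 0}.
#' @return numeric vector of pi charges, one per atom.
#' @export
huckel_pi_charges <- function(g, omega = 1.4, sigma_charges = NULL) {
  n <- n_atoms(g)
  q <- rep(0, n)
  sys <- .pi_system(g)
  idx <- which(sys$member)
  if (length(idx) < 2) return(q)
  if (omega != 0 && is.null(sigma_charges))
    sigma_charges <- peoe_charges(g)$q_heavy
  label <- paste0(sys$elem, ".", sys$role)
  for (piece in .pi_fragments(g, idx)) {
    if (length(piece) < 2) next
    m <- length(piece)
    H <- matrix(0, m, m)
    for (a in seq_len(m)) {
      i <- piece[a]
      H[a, a] <- .huckel_h_value(g, sys, i, omega, sigma_charges)
    }
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
      ai <- match(i, piece); aj <- match(j, piece)
      if (is.na(ai) || is.na(aj)) next
      H[ai, aj] <- H[aj, ai] <- .huckel_k(label[i], label[j])
    }
    ne <- sum(sys$nelec[piece])
    eig <- eigen(H, symmetric = TRUE)
    # E = alpha + x beta with beta < 0: larger x = more stable
    vals <- eig$values
    vecs <- eig$vectors
    occ <- rep(0, m)
    left <- ne
    oi <- 1L
    while (left > 0 && oi <= m) {
      shell <- which(abs(vals - vals[oi]) < 1e-9)
      shell <- shell[shell >= oi]
      cap <- 2 * length(shell)
      fill <- min(left, cap)
      occ[shell] <- fill / length(shell)
      left <- left - fill
      oi <- max(shell) + 1L
    }
    pop <- as.numeric((vecs^2) %*% occ)
    q[piece] <- sys$nelec[piece] - pop
  }
  q
}

# connected components of the pi system (BFS over bonds among members)
.pi_fragments <- function(g, idx) {
  memb <- logical(n_atoms(g))
  memb[idx] <- TRUE
  seen <- logical(n_atoms(g))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- atom_neighbours(g, v)
      for (w in nb$atom) if (memb[w] && !seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}
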