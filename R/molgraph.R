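# Internal molecular-graph representation.
#
# Structures are parsed with Open Babel (via ChemmineOB): a single conversion
# of each input SMILES to MOL2 supplies the aromaticity perception used
# throughout the package, and a parallel conversion to V2000 molfile supplies
# kekulized integer bond orders and formal charges.  Both conversions preserve
# the input atom order, so the two views are merged positionally.  The graph
# itself is a pair of data frames (atoms, bonds); all downstream chemistry
# (fragmentation, probe assembly, charge models) operates on it.

STANDARD_VALENCE <- c(
  "B" = 3, "C" = 4, "N" = 3, "O" = 2, "F" = 1, "Si" = 4, "P" = 3,
  "S" = 2, "Cl" = 1, "Se" = 2, "Br" = 1, "I" = 1, "H" = 1, "*" = 0
)
# elements with an expandable valence shell: smallest standard valence that
# accommodates the drawn bonds is used (S in sulfones, P in phosphates)
HYPERVALENT <- list(S = c(2, 4, 6), P = c(3, 5), Se = c(2, 4, 6))

HALOGENS <- c("F", "Cl", "Br", "I")

ob_convert <- function(from, to, text) {
  ChemmineOB::convertFormat(from, to, source = text,
                            options = data.frame(names = character(0),
                                                 args = character(0)))
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses Open Babel for SMILES interpretation and aromaticity perception, and
#' returns a light-weight graph: a data frame of atoms (element, aromaticity,
#' formal charge, implicit hydrogen count) and a data frame of bonds
#' (endpoints, kekulized integer order, aromatic and ring flags).  The
#' attachment wildcard \code{*} is carried as element \code{"*"} with
#' valence 0.
#'
#' @param smiles a single SMILES string.
#' @return an object of class \code{molgraph}, or an error if the string does
#'   not parse to a valid molecular graph.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  smi <- trimws(smiles)
  if (!nzchar(smi)) stop("empty SMILES string")
  if (grepl("[ \t]", smi)) stop("SMILES must not contain whitespace")
  sdf <- ob_convert("SMI", "SDF", paste0(smi, " m\n"))
  if (!nzchar(sdf)) stop("unparseable SMILES: ", smiles)
  mol2 <- ob_convert("SMI", "MOL2", paste0(smi, " m\n"))
  g <- .merge_blocks(.parse_molfile(sdf), .parse_mol2(mol2))
  g$smiles <- smi
  g
}

.parse_molfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[seq_len(natoms) + 4L]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(natoms)
  if (nbonds > 0) {
    bond_lines <- lines[seq_len(nbonds) + 4L + natoms]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)),
                             " +")[[1]])
    idx <- f[seq(1, length(f), by = 2)]
    charge[idx] <- f[seq(2, length(f), by = 2)]
  }
  list(element = element, charge = charge,
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

.parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sec <- cumsum(grepl("^@<TRIPOS>", lines))
  tags <- lines[grepl("^@<TRIPOS>", lines)]
  atom_sec <- which(tags == "@<TRIPOS>ATOM")
  bond_sec <- which(tags == "@<TRIPOS>BOND")
  atom_lines <- lines[sec == atom_sec & !grepl("^@", lines)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  atype <- vapply(strsplit(trimws(atom_lines), " +"), `[`, "", 6L)
  bond_ar <- logical(0)
  b1 <- b2 <- integer(0)
  if (length(bond_sec)) {
    bond_lines <- lines[sec == bond_sec & !grepl("^@", lines)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    bf <- strsplit(trimws(bond_lines), " +")
    b1 <- as.integer(vapply(bf, `[`, "", 2L))
    b2 <- as.integer(vapply(bf, `[`, "", 3L))
    bond_ar <- vapply(bf, `[`, "", 4L) == "ar"
  }
  list(atom_type = atype,
       bonds = data.frame(a1 = b1, a2 = b2, aromatic = bond_ar))
}

.merge_blocks <- function(sdf, mol2) {
  n <- length(sdf$element)
  if (length(mol2$atom_type) != n)
    stop("internal: atom count mismatch between molfile and MOL2 views")
  aromatic <- grepl("\\.ar$", mol2$atom_type)
  bonds <- sdf$bonds
  # align MOL2 aromatic flags onto molfile bonds via unordered endpoint keys
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ar <- setNames(mol2$bonds$aromatic, key(mol2$bonds$a1, mol2$bonds$a2))
  bonds$aromatic <- unname(ar[key(bonds$a1, bonds$a2)])
  bonds$aromatic[is.na(bonds$aromatic)] <- FALSE
  g <- structure(list(
    atoms = data.frame(element = sdf$element, charge = sdf$charge,
                       aromatic = aromatic),
    bonds = bonds
  ), class = "molgraph")
  g <- .annotate_rings(g)
  # an Open Babel "ar" bond is only taken as aromatic when it closes an
  # aromatic ring (carboxylate C-O pairs are also typed "ar" in MOL2)
  g$bonds$aromatic <- g$bonds$aromatic & g$bonds$ring &
    g$atoms$aromatic[g$bonds$a1] & g$atoms$aromatic[g$bonds$a2]
  g$atoms$nH <- .implicit_h(g)
  g
}

n_atoms <- function(g) nrow(g$atoms)
n_heavy <- function(g) sum(!g$atoms$element %in% c("H", "*"))

# bonds incident to each atom, as a list of bond indices
.incidence <- function(g) {
  n <- n_atoms(g)
  inc <- vector("list", n)
  if (nrow(g$bonds) == 0) return(inc)
  for (b in seq_len(nrow(g$bonds))) {
    inc[[g$bonds$a1[b]]] <- c(inc[[g$bonds$a1[b]]], b)
    inc[[g$bonds$a2[b]]] <- c(inc[[g$bonds$a2[b]]], b)
  }
  inc
}

# ring bonds = edges whose removal leaves their endpoints connected
# (molecules are small, so the per-bond reachability check is cheap)
.annotate_rings <- function(g) {
  m <- nrow(g$bonds)
  ring <- logical(m)
  if (m > 0) {
    for (b in seq_len(m)) {
      comps <- graph_components(g, drop_bonds = b)
      memb <- integer(n_atoms(g))
      for (ci in seq_along(comps)) memb[comps[[ci]]] <- ci
      ring[b] <- memb[g$bonds$a1[b]] == memb[g$bonds$a2[b]]
    }
  }
  g$bonds$ring <- ring
  g$atoms$ring <- FALSE
  if (m > 0) {
    rb <- g$bonds[g$bonds$ring, ]
    g$atoms$ring[unique(c(rb$a1, rb$a2))] <- TRUE
  }
  g
}

.implicit_h <- function(g) {
  n <- n_atoms(g)
  bondsum <- numeric(n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[b]
      bondsum[g$bonds$a1[b]] <- bondsum[g$bonds$a1[b]] + o
      bondsum[g$bonds$a2[b]] <- bondsum[g$bonds$a2[b]] + o
    }
  }
  nH <- integer(n)
  for (i in seq_len(n)) {
    el <- g$atoms$element[i]
    ch <- g$atoms$charge[i]
    if (el %in% c("H", "*")) next
    if (!el %in% names(STANDARD_VALENCE)) next  # exotic element: no implicit H
    v <- if (el %in% names(HYPERVALENT)) {
      cand <- HYPERVALENT[[el]]
      vv <- cand[cand >= bondsum[i] - ch]
      if (length(vv)) vv[1] else max(cand)
    } else STANDARD_VALENCE[[el]]
    v_eff <- if (el == "C" && ch != 0) 3 else v + ch
    nH[i] <- max(0L, as.integer(round(v_eff - bondsum[i])))
  }
  nH
}

# neighbours of atom i (atom indices) and the connecting bond rows
atom_neighbours <- function(g, i) {
  b <- g$bonds
  hit <- b$a1 == i | b$a2 == i
  data.frame(bond = which(hit),
             atom = ifelse(b$a1[hit] == i, b$a2[hit], b$a1[hit]),
             order = b$order[hit], aromatic = b$aromatic[hit],
             ring = b$ring[hit])
}

# TRUE for carbon atoms double-bonded to at least one oxygen
is_carbonyl_carbon <- function(g, i) {
  if (g$atoms$element[i] != "C") return(FALSE)
  nb <- atom_neighbours(g, i)
  any(nb$order == 2 & g$atoms$element[nb$atom] == "O")
}

# connected components as a list of atom-index vectors (BFS)
graph_components <- function(g, drop_bonds = integer(0)) {
  n <- n_atoms(g)
  bonds <- g$bonds
  if (length(drop_bonds)) bonds <- bonds[-drop_bonds, , drop = FALSE]
  comp <- integer(n)
  cur <- 0L
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
      adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  split(seq_len(n), comp)
}

# induced subgraph on `keep` (atom indices), atoms re-indexed in `keep` order
subgraph <- function(g, keep) {
  idx <- match(seq_len(n_atoms(g)), keep)
  b <- g$bonds[g$bonds$a1 %in% keep & g$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- idx[b$a1]
  b$a2 <- idx[b$a2]
  structure(list(atoms = g$atoms[keep, , drop = FALSE], bonds = b),
            class = "molgraph") -> out
  rownames(out$atoms) <- NULL
  rownames(out$bonds) <- NULL
  out
}

# largest covalent component (ties broken by first occurrence)
largest_component <- function(g) {
  comps <- graph_components(g)
  if (length(comps) == 1L) return(g)
  sizes <- vapply(comps, function(a)
    sum(!g$atoms$element[a] %in% c("H", "*")), 0L)
  subgraph(g, sort(comps[[which.max(sizes)]]))
}

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Write a molecular graph as a kekulized SMILES string
#'
#' Emits uppercase (Kekule) SMILES with explicit double/triple bond symbols;
#' aromatic perception is reapplied on re-parsing, so the output round-trips
#' through \code{\link{parse_smiles}}.  Used internally for fragment and probe
#' assembly; canonical forms are produced by \code{\link{canonical_smiles}}.
#'
#' @param g a \code{molgraph}.
#' @param root atom index to start the traversal from (default 1).
#' @param digit_base first ring-closure digit to use (default 1); fragment
#'   SMILES destined for string concatenation use a higher base so closure
#'   digits cannot collide with those of an attached scaffold.
#' @return a SMILES string.
#' @export
write_smiles <- function(g, root = 1L, digit_base = 1L) {
  n <- n_atoms(g)
  stopifnot(n >= 1)
  inc <- .incidence(g)
  visited_atom <- logical(n)
  used_bond <- logical(max(1L, nrow(g$bonds)))
  # assign ring-closure labels: DFS spanning tree, back edges get digits
  closures <- vector("list", n)   # per atom: list of c(digit, order)
  digit <- digit_base - 1L
  order_sym <- function(o) switch(as.character(o), "1" = "", "2" = "=",
                                  "3" = "#", stop("bad bond order ", o))
  atom_token <- function(i) {
    el <- g$atoms$element[i]
    ch <- g$atoms$charge[i]
    nH <- g$atoms$nH[i]
    if (el == "*") return("[*]")
    plain_ok <- el %in% ORGANIC_SUBSET && ch == 0L
    if (plain_ok) return(el)
    hpart <- if (nH == 1L) "H" else if (nH > 1L) paste0("H", nH) else ""
    cpart <- if (ch > 0L) paste0("+", if (ch > 1) ch else "") else
      if (ch < 0L) paste0("-", if (ch < -1) -ch else "") else ""
    paste0("[", el, hpart, cpart, "]")
  }
  # first pass: DFS spanning tree; unused bonds become ring closures
  dfs_children <- vector("list", n)  # bond indices in traversal order
  stack <- root
  visited_atom[root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (b in inc[[v]]) {
      if (used_bond[b]) next
      w <- if (g$bonds$a1[b] == v) g$bonds$a2[b] else g$bonds$a1[b]
      if (!visited_atom[w]) {
        used_bond[b] <- TRUE
        visited_atom[w] <- TRUE
        dfs_children[[v]] <- c(dfs_children[[v]], b)
        stack <- c(stack, w)
      }
    }
  }
  if (!all(visited_atom))
    stop("write_smiles requires a connected graph")
  # back edges = unused bonds
  for (b in which(!used_bond & seq_along(used_bond) <= nrow(g$bonds))) {
    digit <- digit + 1L
    if (digit > 9L && digit_base > 1L)
      stop("ring-closure digits exhausted")
    lab <- if (digit <= 9L) as.character(digit) else paste0("%", digit)
    o <- g$bonds$order[b]
    closures[[g$bonds$a1[b]]] <- c(closures[[g$bonds$a1[b]]],
                                   list(c(lab, order_sym(o))))
    closures[[g$bonds$a2[b]]] <- c(closures[[g$bonds$a2[b]]],
                                   list(c(lab, "")))
  }
  # recursive emit (molecules here are small; recursion depth is fine)
  emit <- function(v) {
    out <- atom_token(v)
    for (cl in closures[[v]]) out <- paste0(out, cl[2], cl[1])
    kids <- dfs_children[[v]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        b <- kids[k]
        w <- if (g$bonds$a1[b] == v) g$bonds$a2[b] else g$bonds$a1[b]
        part <- paste0(order_sym(g$bonds$order[b]), emit(w))
        out <- if (k < length(kids)) paste0(out, "(", part, ")")
               else paste0(out, part)
      }
    }
    out
  }
  emit(root)
}

#' Canonical SMILES for one or more structures
#'
#' Canonicalization is delegated to Open Babel's canonical SMILES writer, so
#' two SMILES describing the same molecular graph (including attachment-marked
#' fragments written from different atom orders) map to the same string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, \code{NA} for entries that do
#'   not parse.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(smiles[idx], " i", seq_along(idx), collapse = "\n")
  res <- ob_convert("SMI", "CAN", paste0(src, "\n"))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < length(idx)) {
    # a bad entry aborts the batch conversion: fall back to per-structure
    for (k in idx) {
      r <- ob_convert("SMI", "CAN", paste0(smiles[k], " x\n"))
      r <- strsplit(r, "[\t\n ]")[[1]]
      if (length(r) && nzchar(r[1])) out[k] <- r[1]
    }
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi_out <- vapply(parts, `[`, "", 1L)
  ids <- as.integer(sub("^i", "", vapply(parts, `[`, "", 2L)))
  out[idx[ids]] <- trimws(smi_out)
  out
}
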