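# Rule-based substituent extraction.
#
# A bond is "chemically activated" (breakable) when it is a single, acyclic,
# non-aromatic bond between two heavy atoms and at least one of the following
# holds: the endpoints differ in ring membership (ring--nonring bond); one
# endpoint is carbon and the other a heteroatom; either endpoint carries a
# double or triple bond to a third atom (carbonyls, nitriles, vinyls...).
# Aromatic bonds never count as multiple bonds for the adjacency rule --
# attachment to an aromatic system is already covered by the ring--nonring
# rule.  Cuts are made one bond at a time; both fragments of a cut are
# candidate substituents, each annotated with the atom it was attached to on
# the other fragment.

#' Is a bond breakable under the fragmentation rules?
#'
#' @param g a \code{molgraph}.
#' @param bond bond index into \code{g$bonds}.
#' @param cut_hetero_hetero also allow cutting single acyclic bonds between
#'   two heteroatoms (for example N-N, S-S) even when no other rule fires;
#'   default \code{FALSE}.
#' @return \code{TRUE} or \code{FALSE}; total over all bonds.
#' @export
is_breakable <- function(g, bond, cut_hetero_hetero = FALSE) {
  b <- g$bonds[bond, ]
  if (b$order != 1L || b$ring || b$aromatic) return(FALSE)
  e1 <- g$atoms$element[b$a1]
  e2 <- g$atoms$element[b$a2]
  if (e1 %in% c("H", "*") || e2 %in% c("H", "*")) return(FALSE)
  if (g$atoms$ring[b$a1] != g$atoms$ring[b$a2]) return(TRUE)
  het1 <- !e1 %in% c("C", "H", "*")
  het2 <- !e2 %in% c("C", "H", "*")
  if ((e1 == "C" && het2) || (e2 == "C" && het1)) return(TRUE)
  if (cut_hetero_hetero && het1 && het2) return(TRUE)
  # adjacency to a multiple bond on either endpoint
  for (a in c(b$a1, b$a2)) {
    nb <- atom_neighbours(g, a)
    nb <- nb[nb$bond != bond, , drop = FALSE]
    if (any(nb$order >= 2L & !nb$aromatic)) return(TRUE)
  }
  FALSE
}

# attachment context of atom i: the atom on the retained side of the cut
.attachment_context <- function(g, i) {
  list(element = g$atoms$element[i],
       aromatic = g$atoms$aromatic[i],
       carbonyl = is_carbonyl_carbon(g, i))
}

# build the attachment-marked fragment graph for component atoms `side`,
# with the wildcard bonded to `cut_atom` (an atom inside `side`)
.fragment_graph <- function(g, side, cut_atom) {
  side <- sort(side)
  sub <- subgraph(g, side)
  root_local <- match(cut_atom, side)
  star <- nrow(sub$atoms) + 1L
  sub$atoms <- rbind(sub$atoms,
                     data.frame(element = "*", charge = 0L, aromatic = FALSE,
                                ring = FALSE, nH = 0L))
  sub$bonds <- rbind(sub$bonds,
                     data.frame(a1 = root_local, a2 = star, order = 1L,
                                aromatic = FALSE, ring = FALSE))
  rownames(sub$atoms) <- NULL
  list(graph = sub, star = star)
}

# raw (not yet canonicalized) occurrences for one molecule
.extract_raw <- function(g, source_id, max_heavy, cut_hetero_hetero) {
  occ <- list()
  nb_bonds <- nrow(g$bonds)
  if (nb_bonds == 0) return(occ)
  for (b in seq_len(nb_bonds)) {
    if (!is_breakable(g, b, cut_hetero_hetero)) next
    comps <- graph_components(g, drop_bonds = b)
    if (length(comps) != 2L) next   # defensive; acyclic cuts always split
    ends <- c(g$bonds$a1[b], g$bonds$a2[b])
    for (k in 1:2) {
      keep_atom <- ends[k]
      other_atom <- ends[3 - k]
      side <- comps[[which(vapply(comps, function(a) keep_atom %in% a,
                                  TRUE))]]
      heavy <- sum(!g$atoms$element[side] %in% c("H", "*"))
      if (heavy < 1L || heavy > max_heavy) next
      fg <- .fragment_graph(g, side, keep_atom)
      ctx <- .attachment_context(g, other_atom)
      occ[[length(occ) + 1L]] <- list(
        raw = write_smiles(fg$graph, root = fg$star, digit_base = 2L),
        heavy = heavy, source_id = source_id,
        element = ctx$element, aromatic = ctx$aromatic,
        carbonyl = ctx$carbonyl)
    }
  }
  occ
}

.occ_frame <- function(occ) {
  if (!length(occ)) {
    return(data.frame(smiles = character(0), heavy_atoms = integer(0),
                      source_id = character(0), att_element = character(0),
                      att_aromatic = logical(0), att_carbonyl = logical(0),
                      att_category = character(0)))
  }
  data.frame(
    smiles = vapply(occ, `[[`, "", "raw"),
    heavy_atoms = vapply(occ, `[[`, 0L, "heavy"),
    source_id = vapply(occ, `[[`, "", "source_id"),
    att_element = vapply(occ, `[[`, "", "element"),
    att_aromatic = vapply(occ, `[[`, TRUE, "aromatic"),
    att_carbonyl = vapply(occ, `[[`, TRUE, "carbonyl"))
}

#' Extract substituent occurrences from one molecule
#'
#' Every breakable bond is cut in turn; each resulting fragment with at most
#' \code{max_heavy} heavy atoms yields one occurrence, annotated with the
#' attachment context (the atom on the other fragment).
#'
#' @param molecule SMILES string or \code{molgraph}.
#' @param source_id identifier recorded on each occurrence.
#' @param max_heavy heavy-atom cap for a fragment to count as a substituent
#'   (default 12).
#' @param cut_hetero_hetero see \code{\link{is_breakable}}.
#' @return data frame of occurrences (canonical fragment SMILES, heavy-atom
#'   count, source id, attachment element/aromatic/carbonyl flags and
#'   category), sorted by canonical form; empty when no bond is breakable.
#' @export
extract_substituents <- function(molecule, source_id = "mol1",
                                 max_heavy = 12L,
                                 cut_hetero_hetero = FALSE) {
  g <- if (inherits(molecule, "molgraph")) molecule else
    parse_smiles(molecule)
  df <- .occ_frame(.extract_raw(g, source_id, max_heavy, cut_hetero_hetero))
  if (nrow(df)) {
    raw_unique <- unique(df$smiles)
    can <- canonical_smiles(raw_unique)
    df$smiles <- can[match(df$smiles, raw_unique)]
    df$att_category <- attachment_category(df$att_element, df$att_aromatic,
                                           df$att_carbonyl)
    df <- df[order(df$smiles, df$source_id), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$att_category <- character(0)
  }
  df
}

.ATT_LEVELS <- c("C", "c", "N,n", "O", "S", "C(=O)*", "X", "other")
.ATT_COLS <- c("att_C", "att_c", "att_Nn", "att_O", "att_S",
               "att_carbonyl", "att_X", "att_other")

#' Fragment a corpus into a substituent catalog
#'
#' Runs \code{\link{extract_substituents}} over a corpus and aggregates
#' occurrences into unique attachment-marked substituents.
#' \code{molecule_frequency} counts distinct source molecules (a molecule
#' contributes once however often the substituent recurs in it);
#' \code{occurrence_count} counts every cut.  Entries below
#' \code{min_molecule_freq} stay in the catalog (raw statistics need them);
#' \code{\link{common_substituents}} gives the thresholded view.
#'
#' @param molecules data frame with columns \code{id} and \code{smiles} (as
#'   returned by \code{\link{read_molecule_table}}), or a character vector of
#'   SMILES (ids are taken from names, or generated).
#' @param max_heavy heavy-atom cap, default 12.
#' @param min_molecule_freq frequency threshold defining the "common" view,
#'   default 50 molecules.
#' @param bioactive_only drop molecules whose \code{bioactive} flag is not
#'   \code{TRUE} before fragmenting.
#' @param cut_hetero_hetero see \code{\link{is_breakable}}.
#' @return a \code{substituent_catalog} data frame, one row per unique
#'   substituent, with frequency counts, attachment-category profile columns,
#'   root/level-2 classes, and (unannotated) \code{pi}/\code{sigma} columns;
#'   attributes \code{corpus_size} and \code{min_molecule_freq}.
#' @export
fragment_corpus <- function(molecules, max_heavy = 12L,
                            min_molecule_freq = 50L,
                            bioactive_only = FALSE,
                            cut_hetero_hetero = FALSE) {
  if (is.character(molecules)) {
    ids <- names(molecules)
    if (is.null(ids))
      ids <- sprintf("mol%d", seq_along(molecules))
    molecules <- data.frame(id = ids, smiles = unname(molecules))
  }
  if (bioactive_only) {
    if (!"bioactive" %in% names(molecules))
      stop("bioactive_only requires a 'bioactive' column")
    molecules <- molecules[molecules$bioactive %in% TRUE, , drop = FALSE]
  }
  all_occ <- vector("list", nrow(molecules))
  n_failed <- 0L
  for (i in seq_len(nrow(molecules))) {
    g <- tryCatch(parse_smiles(molecules$smiles[i]), error = function(e) NULL)
    if (is.null(g)) { n_failed <- n_failed + 1L; next }
    all_occ[[i]] <- .occ_frame(
      .extract_raw(g, molecules$id[i], max_heavy, cut_hetero_hetero))
  }
  if (n_failed)
    warning(n_failed, " molecule(s) failed to parse and were skipped")
  occ <- do.call(rbind, all_occ[!vapply(all_occ, is.null, TRUE)])
  catalog <- .aggregate_occurrences(occ, corpus_size = nrow(molecules),
                                    min_molecule_freq = min_molecule_freq)
  catalog
}

# shared aggregation: occurrence frame -> catalog
.aggregate_occurrences <- function(occ, corpus_size, min_molecule_freq) {
  empty <- is.null(occ) || nrow(occ) == 0L
  if (!empty) {
    raw_unique <- unique(occ$smiles)
    can <- canonical_smiles(raw_unique)
    occ$smiles <- can[match(occ$smiles, raw_unique)]
    if (!"att_category" %in% names(occ))
      occ$att_category <- attachment_category(occ$att_element,
                                              occ$att_aromatic,
                                              occ$att_carbonyl)
    key <- factor(occ$smiles)
    mol_freq <- vapply(split(occ$source_id, key),
                       function(s) length(unique(s)), 0L)
    occ_count <- as.integer(table(key))
    heavy <- vapply(split(occ$heavy_atoms, key), `[`, 0L, 1L)
    cat_tab <- table(key, factor(occ$att_category, levels = .ATT_LEVELS))
    catalog <- data.frame(smiles = levels(key), heavy_atoms = heavy,
                          molecule_frequency = unname(mol_freq),
                          occurrence_count = occ_count)
    prof <- as.data.frame.matrix(cat_tab)
    names(prof) <- .ATT_COLS
    catalog <- cbind(catalog, prof)
    cls <- substituent_classes(catalog$smiles)
    catalog$root_class <- cls$root_class
    catalog$level2_class <- cls$level2_class
    catalog$pi <- NA_real_
    catalog$sigma <- NA_real_
    ord <- order(-catalog$molecule_frequency, catalog$smiles)
    catalog <- catalog[ord, , drop = FALSE]
    rownames(catalog) <- NULL
  } else {
    catalog <- data.frame(smiles = character(0), heavy_atoms = integer(0),
                          molecule_frequency = integer(0),
                          occurrence_count = integer(0))
    for (cl in .ATT_COLS) catalog[[cl]] <- integer(0)
    catalog$root_class <- character(0)
    catalog$level2_class <- character(0)
    catalog$pi <- numeric(0)
    catalog$sigma <- numeric(0)
    catalog <- catalog[, .CATALOG_COLUMNS[.CATALOG_COLUMNS %in%
                                            names(catalog)]]
  }
  catalog <- catalog[, .CATALOG_COLUMNS[.CATALOG_COLUMNS %in% names(catalog)]]
  class(catalog) <- c("substituent_catalog", "data.frame")
  attr(catalog, "corpus_size") <- corpus_size
  attr(catalog, "min_molecule_freq") <- min_molecule_freq
  catalog
}

#' Common-substituent view of a catalog
#'
#' @param catalog a \code{substituent_catalog}.
#' @param min_molecule_freq threshold; defaults to the one recorded on the
#'   catalog (50 unless overridden at extraction time).
#' @return the catalog restricted to substituents present in at least
#'   \code{min_molecule_freq} distinct molecules.
#' @export
common_substituents <- function(catalog,
                                min_molecule_freq =
                                  attr(catalog, "min_molecule_freq")) {
  if (is.null(min_molecule_freq)) min_molecule_freq <- 50L
  out <- catalog[catalog$molecule_frequency >= min_molecule_freq, ,
                 drop = FALSE]
  rownames(out) <- NULL
  for (a in c("corpus_size", "min_molecule_freq"))
    attr(out, a) <- attr(catalog, a)
  class(out) <- class(catalog)
  out
}
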