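# Root-atom / second-shell classification and frequency statistics.
#
# Classes are printed in a SMILES-like grammar: uppercase symbols are
# aliphatic, lowercase aromatic, ":" marks an aromatic bond, "=" a double
# bond, "#" a triple bond and "-" a single bond; halogens are pooled as "X".
# ASCII hyphens are used throughout (e.g. "R-C(=O)-N", "R-c(:c):c").

.SYMBOL_RANK <- c("C" = 1, "c" = 2, "N" = 3, "n" = 4, "O" = 5, "S" = 6,
                  "X" = 7)

.class_symbol <- function(element, aromatic) {
  ifelse(element %in% HALOGENS, "X",
         ifelse(aromatic, tolower(element), element))
}

#' Attachment-point category
#'
#' Maps the skeleton atom a substituent is bonded to onto the categories used
#' in attachment profiles: carbonyl carbon \code{"C(=O)*"} (taking precedence
#' over plain carbon), aromatic carbon \code{"c"}, aliphatic carbon
#' \code{"C"}, nitrogen \code{"N,n"} (aromatic and aliphatic merged), oxygen
#' \code{"O"}, sulfur \code{"S"}, halogen \code{"X"}, and \code{"other"}.
#'
#' @param element atomic symbol(s) of the attachment atom.
#' @param aromatic logical, aromatic flag(s).
#' @param carbonyl logical, \code{TRUE} when the atom is a carbon
#'   double-bonded to oxygen.
#' @return character vector of categories.
#' @export
attachment_category <- function(element, aromatic, carbonyl) {
  out <- rep("other", length(element))
  out[element == "C"] <- ifelse(aromatic[element == "C"], "c", "C")
  out[element == "C" & carbonyl] <- "C(=O)*"
  out[element == "N"] <- "N,n"
  out[element == "O"] <- "O"
  out[element == "S"] <- "S"
  out[element %in% HALOGENS] <- "X"
  out
}

# root atom (the substituent atom bonded to the wildcard) of a fragment graph
.root_atom <- function(g) {
  star <- which(g$atoms$element == "*")
  if (length(star) != 1L)
    stop("fragment must contain exactly one attachment point")
  atom_neighbours(g, star)$atom
}

#' Root-atom class of a substituent
#'
#' The level-1 class \code{"R-E"} where E is the symbol of the atom bonded to
#' the attachment point: lowercase when aromatic (\code{R-c}, \code{R-n}),
#' halogens pooled as \code{R-X}.
#'
#' @param substituent attachment-marked SMILES or \code{molgraph}.
#' @return class string, e.g. \code{"R-C"}.
#' @export
root_class <- function(substituent) {
  g <- if (inherits(substituent, "molgraph")) substituent else
    parse_smiles(substituent)
  r <- .root_atom(g)
  paste0("R-", .class_symbol(g$atoms$element[r], g$atoms$aromatic[r]))
}

# render one neighbour: bond prefix + class symbol
.neighbour_token <- function(g, bond_order, bond_aromatic, atom) {
  sym <- .class_symbol(g$atoms$element[atom], g$atoms$aromatic[atom])
  pre <- if (bond_aromatic) ":" else
    switch(as.character(bond_order), "1" = "-", "2" = "=", "3" = "#", "-")
  paste0(pre, sym)
}

# neighbours of `atom` excluding `exclude`, ordered canonically:
# carbonyl oxygen first, then fixed symbol precedence, then symbol
.ordered_neighbours <- function(g, atom, exclude) {
  nb <- atom_neighbours(g, atom)
  nb <- nb[!nb$atom %in% exclude, , drop = FALSE]
  if (!nrow(nb)) return(nb)
  sym <- .class_symbol(g$atoms$element[nb$atom], g$atoms$aromatic[nb$atom])
  carbonyl_o <- g$atoms$element[nb$atom] == "O" & nb$order == 2 &
    g$atoms$element[atom] == "C"
  rank <- .SYMBOL_RANK[sym]
  rank[is.na(rank)] <- 8
  rank[carbonyl_o] <- 0
  nb[order(rank, sym), , drop = FALSE]
}

# rendering overrides: neighbour multisets whose conventional printed form
# deviates from the plain precedence order (aromatic heteroatom shown first
# in mixed aromatic shells, as in "R-c(:n):c")
.RENDER_OVERRIDE <- list(
  "c|:c,:n" = c(":n", ":c"),
  "n|:c,:n" = c(":n", ":c")
)

# assemble "R-E(tok1)(tok2)tokN" with all but the last neighbour in parens
.render_pattern <- function(root_sym, tokens) {
  if (!length(tokens)) return(paste0("R-", root_sym))
  key <- paste0(root_sym, "|", paste(sort(tokens), collapse = ","))
  if (!is.null(.RENDER_OVERRIDE[[key]])) tokens <- .RENDER_OVERRIDE[[key]]
  n <- length(tokens)
  inner <- if (n > 1)
    paste0("(", tokens[-n], ")", collapse = "") else ""
  paste0("R-", root_sym, inner, tokens[n])
}

#' Second-shell class of a substituent
#'
#' Extends the root class with the root atom's heavy neighbours inside the
#' substituent, rendered with their bond annotation and in canonical order
#' (carbonyl oxygen first, then C, c, N, n, O, S, X).  With \code{depth = 3}
#' each neighbour is expanded one further shell, which reproduces chain
#' patterns such as \code{"R-C-C-O"}.
#'
#' @param substituent attachment-marked SMILES or \code{molgraph}.
#' @param depth 2 (default) or 3.
#' @return class string, e.g. \code{"R-C(=O)-N"}; a root with no heavy
#'   neighbours gives the root class itself.
#' @export
level2_class <- function(substituent, depth = 2L) {
  stopifnot(depth %in% c(2L, 3L))
  g <- if (inherits(substituent, "molgraph")) substituent else
    parse_smiles(substituent)
  star <- which(g$atoms$element == "*")
  r <- .root_atom(g)
  root_sym <- .class_symbol(g$atoms$element[r], g$atoms$aromatic[r])
  nb <- .ordered_neighbours(g, r, exclude = star)
  tokens <- character(nrow(nb))
  for (k in seq_len(nrow(nb))) {
    tok <- .neighbour_token(g, nb$order[k], nb$aromatic[k], nb$atom[k])
    if (depth == 3L) {
      nb2 <- .ordered_neighbours(g, nb$atom[k], exclude = c(r, star))
      if (nrow(nb2)) {
        tok2 <- vapply(seq_len(nrow(nb2)), function(j)
          .neighbour_token(g, nb2$order[j], nb2$aromatic[j], nb2$atom[j]), "")
        n2 <- length(tok2)
        inner <- if (n2 > 1) paste0("(", tok2[-n2], ")", collapse = "") else ""
        tok <- paste0(tok, inner, tok2[n2])
      }
    }
    tokens[k] <- tok
  }
  .render_pattern(root_sym, tokens)
}

#' Root and level-2 classes for a vector of substituents
#'
#' @param smiles character vector of attachment-marked SMILES.
#' @return data frame with columns \code{root_class} and \code{level2_class}.
#' @export
substituent_classes <- function(smiles) {
  root <- character(length(smiles))
  lvl2 <- character(length(smiles))
  for (k in seq_along(smiles)) {
    g <- parse_smiles(smiles[k])
    root[k] <- root_class(g)
    lvl2[k] <- level2_class(g)
  }
  data.frame(root_class = root, level2_class = lvl2)
}

#' Classification table with attachment profiles
#'
#' Aggregates a catalog into the root-atom / second-shell classification with
#' per-class attachment-point breakdowns.  With the default
#' occurrence weighting every extracted occurrence counts (a substituent
#' present a thousand times contributes a thousand times); with
#' \code{weighting = "unique"} each unique substituent contributes once and
#' its attachment profile is normalized to one before summing.
#'
#' @param catalog a \code{substituent_catalog}.
#' @param weighting \code{"occurrence"} (default) or \code{"unique"}.
#' @return data frame with columns \code{level} (\code{"root"} or
#'   \code{"level2"}), \code{root_class}, \code{class}, \code{percent} and one
#'   \code{att_*} percentage column per attachment category, sorted by
#'   descending share (level-2 rows nested under their root class).
#' @export
aggregate_profiles <- function(catalog,
                               weighting = c("occurrence", "unique")) {
  weighting <- match.arg(weighting)
  if (!nrow(catalog)) {
    out <- data.frame(level = character(0), root_class = character(0),
                      class = character(0), percent = numeric(0))
    for (cl in .ATT_COLS) out[[cl]] <- numeric(0)
    return(out)
  }
  w <- if (weighting == "occurrence") catalog$occurrence_count else
    rep(1, nrow(catalog))
  prof <- as.matrix(catalog[, .ATT_COLS, drop = FALSE])
  if (weighting == "unique") {
    tot <- rowSums(prof)
    tot[tot == 0] <- 1
    prof <- prof / tot
  }
  total <- sum(w)
  one_level <- function(cls, root_of_cls) {
    agg_w <- tapply(w, cls, sum)
    agg_p <- rowsum(prof * 1, cls)
    share <- 100 * as.numeric(agg_w) / total
    att <- 100 * agg_p / pmax(rowSums(agg_p), .Machine$double.eps)
    data.frame(class = names(agg_w), root_class = root_of_cls[names(agg_w)],
               percent = share, att, check.names = FALSE,
               row.names = NULL)
  }
  root_of_root <- setNames(unique(catalog$root_class),
                           unique(catalog$root_class))
  lvl1 <- one_level(catalog$root_class, root_of_root)
  lvl1$level <- "root"
  root_of_l2 <- tapply(catalog$root_class, catalog$level2_class, `[`, 1L)
  lvl2 <- one_level(catalog$level2_class, root_of_l2)
  lvl2$level <- "level2"
  # order: root classes by descending share; level-2 rows inside their root
  lvl1 <- lvl1[order(-lvl1$percent, lvl1$class), , drop = FALSE]
  pieces <- list()
  for (rc in lvl1$class) {
    pieces[[length(pieces) + 1L]] <- lvl1[lvl1$class == rc, , drop = FALSE]
    sub <- lvl2[lvl2$root_class == rc, , drop = FALSE]
    sub <- sub[order(-sub$percent, sub$class), , drop = FALSE]
    if (nrow(sub)) pieces[[length(pieces) + 1L]] <- sub
  }
  out <- do.call(rbind, pieces)
  out <- out[, c("level", "root_class", "class", "percent", .ATT_COLS)]
  rownames(out) <- NULL
  out
}

#' Frequency-distribution summary of a catalog
#'
#' Summarizes the long-tail structure of substituent frequencies: how many
#' unique substituents there are, how many occurrences they account for, the
#' singleton count and fraction (substituents present in exactly one
#' molecule), and how many substituents are present in more than given
#' fractions of the corpus.
#'
#' @param catalog a \code{substituent_catalog} (full, unthresholded view).
#' @param corpus_size number of molecules the catalog was extracted from;
#'   defaults to the value recorded on the catalog.
#' @param thresholds corpus fractions for the "present in more than"
#'   counts; default 1\% and 0.1\%.
#' @return a list of class \code{frequency_summary}.
#' @export
frequency_summary <- function(catalog,
                              corpus_size = attr(catalog, "corpus_size"),
                              thresholds = c(0.01, 0.001)) {
  if (is.null(corpus_size) || !is.finite(corpus_size) || corpus_size <= 0)
    stop("corpus_size must be a positive number")
  unique_count <- nrow(catalog)
  singleton_count <- sum(catalog$molecule_frequency == 1L)
  n_above <- vapply(thresholds, function(th)
    sum(catalog$molecule_frequency > th * corpus_size), 0L)
  names(n_above) <- paste0(thresholds * 100, "%")
  structure(list(
    unique_count = unique_count,
    total_occurrences = sum(catalog$occurrence_count),
    singleton_count = singleton_count,
    singleton_fraction = if (unique_count) singleton_count / unique_count
                         else NaN,
    n_above_fraction = n_above,
    corpus_size = corpus_size
  ), class = "frequency_summary")
}

#' @export
print.frequency_summary <- function(x, ...) {
  cat("Substituent frequency summary\n")
  cat(sprintf("  corpus size        : %d molecules\n", x$corpus_size))
  cat(sprintf("  unique substituents: %d\n", x$unique_count))
  cat(sprintf("  total occurrences  : %d\n", x$total_occurrences))
  cat(sprintf("  singletons         : %d (%.1f%%)\n", x$singleton_count,
              100 * x$singleton_fraction))
  for (nm in names(x$n_above_fraction))
    cat(sprintf("  present in > %-5s : %d\n", nm, x$n_above_fraction[[nm]]))
  invisible(x)
}
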