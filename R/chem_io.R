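# Reading and writing molecule and substituent tables.
#
# Input corpora are SMILES line-notation files: one structure per line,
# "SMILES <ws> id [<ws> activity]".  Substituent catalogs are written as TSV
# with a fixed header; numeric fields are printed at full precision so the
# writer/reader pair round-trips exactly.

#' Read a molecule table in SMILES line notation
#'
#' Each line holds a SMILES string, a whitespace-separated identifier and an
#' optional numeric activity value (interpreted in micromolar).  Unparseable
#' lines are skipped and reported via the \code{skipped} attribute rather than
#' aborting the read.  Multi-component structures (salts, solvates) are
#' reduced to their largest covalent component.
#'
#' @param file path to a .smi file, or \code{NULL} when \code{text} is given.
#' @param text character scalar or vector of lines, as an alternative input.
#' @param activity_threshold molecules with activity strictly below this value
#'   are flagged bioactive (default 10, i.e. 10 micromolar in the usual
#'   ChEMBL-style convention).
#' @param header set \code{TRUE} if the first line is a column header; it must
#'   then name its first column \code{smiles} (case-insensitive), otherwise an
#'   error identifies the offending line.
#' @return a data frame with columns \code{id}, \code{smiles} (canonical form
#'   of the kept component), \code{activity} (numeric, \code{NA} when absent)
#'   and \code{bioactive} (logical, \code{NA} when no activity is given),
#'   carrying attribute \code{skipped}: a data frame of rejected lines.
#' @export
read_molecule_table <- function(file = NULL, text = NULL,
                                activity_threshold = 10,
                                header = FALSE) {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lineno <- seq_along(lines)
  if (header && length(lines)) {
    first <- tolower(strsplit(trimws(lines[1]), "[ \t]+")[[1]][1])
    if (!identical(first, "smiles"))
      stop("malformed header on line 1: expected first column 'smiles', got '",
           first, "'")
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    warning("empty molecule table")
    out <- data.frame(id = character(0), smiles = character(0),
                      activity = numeric(0), bioactive = logical(0))
    attr(out, "skipped") <- data.frame(line = integer(0), text = character(0),
                                       reason = character(0))
    return(out)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(fields, `[`, "", 1L)
  id <- vapply(fields, function(f) if (length(f) >= 2) f[2] else NA_character_,
               "")
  id[is.na(id)] <- paste0("mol", lineno[is.na(id)])
  act <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else NA_real_, 0)

  # salt handling: keep the largest covalent component of dotted SMILES
  multi <- grepl(".", smi, fixed = TRUE)
  for (k in which(multi)) {
    g <- tryCatch(largest_component(parse_smiles(smi[k])),
                  error = function(e) NULL)
    smi[k] <- if (is.null(g)) NA_character_ else write_smiles(g)
  }
  can <- canonical_smiles(smi)
  bad <- is.na(can)
  skipped <- data.frame(line = lineno[bad], text = lines[bad],
                        reason = rep("unparseable SMILES", sum(bad)))
  out <- data.frame(id = id[!bad], smiles = can[!bad],
                    activity = act[!bad],
                    bioactive = act[!bad] < activity_threshold)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (nrow(skipped))
    warning(nrow(skipped), " unparseable line(s) skipped")
  out
}

#' Canonical attachment-marked fragment
#'
#' Validates and canonicalizes a substituent written with a single attachment
#' wildcard \code{*}.  The canonical form is invariant under permutation of
#' the input atom order, which is what makes corpus-wide frequency counting of
#' substituents well defined.
#'
#' @param smiles fragment SMILES containing exactly one \code{*} atom bound by
#'   exactly one single bond.
#' @return a list of class \code{substituent_fragment} with elements
#'   \code{smiles} (canonical form) and \code{heavy_atoms} (wildcard and
#'   hydrogens excluded).
#' @export
canonical_substituent <- function(smiles) {
  g <- if (inherits(smiles, "molgraph")) smiles else parse_smiles(smiles)
  star <- which(g$atoms$element == "*")
  if (length(star) != 1L)
    stop("fragment must contain exactly one attachment point, found ",
         length(star))
  nb <- atom_neighbours(g, star)
  if (nrow(nb) != 1L)
    stop("attachment point must have exactly one bond, found ", nrow(nb))
  if (nb$order != 1L)
    stop("attachment bond must be a single bond")
  can <- canonical_smiles(write_smiles(g, root = star, digit_base = 2L))
  structure(list(smiles = can, heavy_atoms = n_heavy(g)),
            class = "substituent_fragment")
}

.CATALOG_COLUMNS <- c("smiles", "heavy_atoms", "molecule_frequency",
                      "occurrence_count", "root_class", "level2_class",
                      "att_C", "att_c", "att_Nn", "att_O", "att_S",
                      "att_carbonyl", "att_X", "att_other", "pi", "sigma")
.CATALOG_NUMERIC <- c("heavy_atoms", "molecule_frequency", "occurrence_count",
                      "att_C", "att_c", "att_Nn", "att_O", "att_S",
                      "att_carbonyl", "att_X", "att_other", "pi", "sigma")

#' Write a substituent catalog as TSV
#'
#' @param catalog a \code{substituent_catalog} data frame.
#' @param file output path.
#' @param columns columns to write; defaults to every catalog column.
#'   Requesting a column absent from the catalog is an error.
#' @return invisibly, the number of data rows written.
#' @export
write_substituent_table <- function(catalog, file,
                                    columns = intersect(.CATALOG_COLUMNS,
                                                        names(catalog))) {
  missing_cols <- setdiff(columns, names(catalog))
  if (length(missing_cols))
    stop("column(s) not present in catalog: ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(catalog)[, columns, drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v)
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g"), "")
    } else {
      out <- as.character(x)
      out[is.na(out)] <- ""
    }
    out
  }
  body <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1L,
                                     dimnames = list(NULL, columns))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(columns, collapse = "\t"), con)
  if (nrow(df))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(nrow(df))
}

#' Read a substituent catalog written by \code{write_substituent_table}
#'
#' @param file TSV path.
#' @return a \code{substituent_catalog} data frame; empty cells become
#'   \code{NA}, numeric columns are restored at full precision.
#' @export
read_substituent_table <- function(file) {
  df <- utils::read.delim(file, sep = "\t", quote = "", comment.char = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = "")
  for (cl in intersect(.CATALOG_NUMERIC, names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  class(df) <- c("substituent_catalog", "data.frame")
  df
}
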