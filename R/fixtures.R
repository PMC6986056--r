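# Seeded synthetic corpora with a long-tail substituent frequency structure.
#
# The generator emulates the one statistical property of bioactive-molecule
# corpora that the pipeline's statistics depend on: a power-law (Zipf)
# frequency distribution of substituents over a fixed pool, planted onto a
# small set of ring scaffolds.  The head of the pool is the fixed, well-known
# ranking of ubiquitous groups (methyl, halogens, methoxy, ...); the
# combinatorial tail is shuffled by the seed.  A manifest records which
# substituent was planted on which molecule, so extraction results can be
# compared against ground truth.

#' Built-in substituent vocabulary
#'
#' Classic Craig-type substituents (halogens, alkyls, ethers, nitro, cyano,
#' trifluoromethyl, amines, acyls, sulfonyl, phenyl...) as attachment-marked
#' SMILES, ordered roughly by their ubiquity in drug-like molecules.
#'
#' @return character vector of attachment-marked SMILES.
#' @export
substituent_vocabulary <- function() {
  c("[*]C", "[*]OC", "[*]F", "[*]Cl", "[*]CC", "[*]O", "[*]N(C)C",
    "[*]C(F)(F)F", "[*]Br", "[*][N+](=O)[O-]", "[*]C#N", "[*]c1ccccc1",
    "[*]C(C)C", "[*]N", "[*]C(=O)OC", "[*]C(=O)N", "[*]C(=O)C", "[*]SC",
    "[*]OCC", "[*]C(=O)O", "[*]S(C)(=O)=O", "[*]I", "[*]C(C)(C)C",
    "[*]NC(C)=O", "[*]OC(F)(F)F", "[*]C=C", "[*]CCC", "[*]N1CCCCC1",
    "[*]N1CCOCC1", "[*]c1ccncc1", "[*]CO", "[*]CN", "[*]C(=O)NC",
    "[*]NC", "[*]OCO", "[*]S")
}

#' Zipf-weighted substituent pool
#'
#' Builds a pool of \code{pool_size} distinct attachment-marked substituents
#' whose sampling weights follow a power law in rank,
#' \code{weight(r) = r^-exponent / sum(r^-exponent)}.  The first ranks are
#' the fixed vocabulary; further entries are generated combinatorially by
#' chain extension of vocabulary tails and assigned to the remaining ranks
#' in a seed-dependent order.
#'
#' @param seed integer seed (shuffles only the combinatorial tail).
#' @param pool_size number of pool entries (>= 10).
#' @param exponent Zipf exponent, must be > 1; default 1.5.
#' @return data frame with columns \code{smiles} (canonical), \code{rank},
#'   \code{weight} (normalized) and \code{heavy_atoms}.
#' @export
zipf_pool <- function(seed = 1L, pool_size = 60L, exponent = 1.5) {
  if (exponent <= 1) stop("zipf exponent must be > 1")
  if (pool_size < 10) stop("pool_size must be >= 10")
  vocab <- substituent_vocabulary()
  tails <- sub("^\\[\\*\\]", "", vocab)
  linkers <- c("C", "CC", "OC", "NC", "C(=O)", "CCC", "CC(C)", "COC")
  ext <- character(0)
  for (ln in linkers)
    ext <- c(ext, paste0("[*]", ln, tails))
  pool <- c(vocab, ext)
  can <- canonical_smiles(pool)
  pool <- pool[!is.na(can)]
  can <- can[!is.na(can)]
  keep <- !duplicated(can)
  pool <- pool[keep]
  can <- can[keep]
  heavy <- nchar(gsub("[^A-Za-z]|H", "", gsub("Cl|Br", "Q", can)))
  ok <- heavy <= 12
  pool <- pool[ok]; can <- can[ok]; heavy <- heavy[ok]
  if (pool_size > length(pool))
    stop("pool_size exceeds the available vocabulary (",
         length(pool), ")")
  n_head <- min(length(vocab), pool_size)
  head_idx <- seq_len(n_head)
  tail_pool <- setdiff(seq_along(pool), head_idx)
  n_tail <- pool_size - n_head
  tail_idx <- integer(0)
  if (n_tail > 0) {
    tail_idx <- .with_seed(seed,
                           tail_pool[sample.int(length(tail_pool), n_tail)])
  }
  idx <- c(head_idx, tail_idx)
  r <- seq_len(pool_size)
  w <- r^(-exponent)
  out <- data.frame(smiles = can[idx], rank = r, weight = w / sum(w),
                    heavy_atoms = heavy[idx])
  rownames(out) <- NULL
  out
}

# run expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.DEFAULT_SCAFFOLDS <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccsc1",
                        "C1CCCCC1", "C1CCNCC1")

#' Corpus generator configuration
#'
#' @param seed integer seed controlling the whole corpus.
#' @param n_molecules number of molecules to generate.
#' @param scaffold_set ring scaffolds (SMILES) decorated by the generator.
#' @param pool_size,zipf_exponent forwarded to \code{\link{zipf_pool}}.
#' @param max_decorations maximum substituents planted per molecule.
#' @return a list of class \code{corpus_config}.
#' @export
corpus_config <- function(seed = 1L, n_molecules = 500L,
                          scaffold_set = .DEFAULT_SCAFFOLDS,
                          pool_size = 60L, zipf_exponent = 1.5,
                          max_decorations = 3L) {
  structure(list(seed = as.integer(seed),
                 n_molecules = as.integer(n_molecules),
                 scaffold_set = scaffold_set,
                 pool_size = as.integer(pool_size),
                 zipf_exponent = zipf_exponent,
                 max_decorations = as.integer(max_decorations)),
            class = "corpus_config")
}

#' Generate a seeded synthetic molecule corpus
#'
#' Each molecule is a scaffold with 1..max_decorations pool substituents
#' planted on distinct hydrogen-bearing ring positions.  Activities are
#' drawn log-uniformly between 0.01 and 100 (micromolar), so roughly three
#' quarters of the corpus is "bioactive" under the usual 10 micromolar
#' cutoff.
#'
#' @param config a \code{corpus_config} (or arguments forwarded to it).
#' @param ... used to build a config when \code{config} is missing.
#' @return data frame with columns \code{id}, \code{smiles},
#'   \code{activity}, \code{bioactive}; attributes \code{manifest} (data
#'   frame: \code{id}, \code{scaffold}, \code{substituent}) and
#'   \code{pool} (the Zipf pool used).
#' @export
generate_corpus <- function(config = corpus_config(...), ...) {
  stopifnot(inherits(config, "corpus_config"))
  pool <- zipf_pool(config$seed, config$pool_size, config$zipf_exponent)
  pool_graphs <- lapply(pool$smiles, parse_smiles)
  scaff_graphs <- lapply(config$scaffold_set, parse_smiles)
  open_pos <- lapply(scaff_graphs, function(g)
    which(g$atoms$nH > 0 & g$atoms$ring))
  usable <- vapply(open_pos, length, 0L) > 0L
  if (!all(usable)) {
    warning("scaffold(s) without open positions skipped: ",
            paste(config$scaffold_set[!usable], collapse = ", "))
    scaff_graphs <- scaff_graphs[usable]
    open_pos <- open_pos[usable]
  }
  n <- config$n_molecules
  .with_seed(config$seed + 1L, {
    scaff_pick <- sample.int(length(scaff_graphs), n, replace = TRUE)
    n_dec <- sample.int(config$max_decorations, n, replace = TRUE)
    activity <- 10^stats::runif(n, -2, 2)
    smiles <- character(n)
    manifest <- vector("list", n)
    for (i in seq_len(n)) {
      g <- scaff_graphs[[scaff_pick[i]]]
      pos <- open_pos[[scaff_pick[i]]]
      k <- min(n_dec[i], length(pos))
      at <- pos[sample.int(length(pos), k)]
      subs <- sample.int(nrow(pool), k, replace = TRUE, prob = pool$weight)
      for (j in seq_len(k)) {
        g <- .plant(g, at[j], pool_graphs[[subs[j]]])
      }
      smiles[i] <- write_smiles(g)
      manifest[[i]] <- data.frame(id = paste0("syn", i),
                                  scaffold =
                                    config$scaffold_set[usable][scaff_pick[i]],
                                  substituent = pool$smiles[subs])
    }
  })
  can <- canonical_smiles(smiles)
  if (anyNA(can))
    stop("internal: generator produced unparseable structures")
  out <- data.frame(id = paste0("syn", seq_len(n)), smiles = can,
                    activity = activity,
                    bioactive = activity < 10)
  attr(out, "manifest") <- do.call(rbind, manifest)
  attr(out, "pool") <- pool
  out
}

# attach fragment (attachment-marked graph) to scaffold atom `at`
.plant <- function(g, at, frag) {
  star <- which(frag$atoms$element == "*")
  keep <- setdiff(seq_len(n_atoms(frag)), star)
  root <- atom_neighbours(frag, star)$atom
  sub <- subgraph(frag, keep)
  off <- n_atoms(g)
  root_new <- off + match(root, keep)
  bonds <- sub$bonds
  bonds$a1 <- bonds$a1 + off
  bonds$a2 <- bonds$a2 + off
  g$atoms <- rbind(g$atoms, sub$atoms)
  g$bonds <- rbind(g$bonds, bonds,
                   data.frame(a1 = at, a2 = root_new, order = 1L,
                              aromatic = FALSE, ring = FALSE))
  rownames(g$atoms) <- NULL
  g$atoms$nH <- .implicit_h(g)
  g
}

#' Write a corpus to a SMILES file
#'
#' @param corpus data frame from \code{\link{generate_corpus}}.
#' @param file output .smi path ("SMILES id activity" per line).
#' @param manifest_file optional TSV path for the planting manifest.
#' @return invisibly, the number of molecules written.
#' @export
write_corpus <- function(corpus, file, manifest_file = NULL) {
  writeLines(paste(corpus$smiles, corpus$id,
                   formatC(corpus$activity, digits = 6, format = "g")),
             file)
  if (!is.null(manifest_file)) {
    mf <- attr(corpus, "manifest")
    if (is.null(mf)) stop("corpus carries no manifest")
    utils::write.table(mf, manifest_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(nrow(corpus))
}
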