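# Shared fixtures and independent oracles.

# Synthetic annotated catalog for navigator tests: properties are plain
# numbers, no chemistry involved.
make_catalog <- function(pi, sigma, freq = rep(10L, length(pi)),
                         smiles = sprintf("[*]S%03d", seq_along(pi)),
                         root_class = rep("R-C", length(pi)),
                         heavy = rep(3L, length(pi))) {
  n <- length(pi)
  df <- data.frame(smiles = smiles, heavy_atoms = heavy,
                   molecule_frequency = freq, occurrence_count = freq,
                   root_class = root_class, level2_class = root_class)
  for (cl in c("att_C", "att_c", "att_Nn", "att_O", "att_S",
               "att_carbonyl", "att_X", "att_other"))
    df[[cl]] <- rep(0L, n)
  df$att_c <- freq
  df$pi <- pi
  df$sigma <- sigma
  class(df) <- c("substituent_catalog", "data.frame")
  attr(df, "corpus_size") <- sum(freq)
  attr(df, "min_molecule_freq") <- 1L
  df
}

# Independent fragment enumeration: for every bond of the molecule, test
# breakability, split the graph by reachability (computed here by boolean
# matrix expansion, not by the package's BFS), and collect canonical
# fragment strings for the sides within the size cap.
oracle_enumerate <- function(smiles, source_id, max_heavy = 12L) {
  g <- parse_smiles(smiles)
  n <- nrow(g$atoms)
  out <- list()
  for (b in seq_len(nrow(g$bonds))) {
    if (!is_breakable(g, b)) next
    A <- matrix(FALSE, n, n)
    keep <- setdiff(seq_len(nrow(g$bonds)), b)
    for (bb in keep) {
      A[g$bonds$a1[bb], g$bonds$a2[bb]] <- TRUE
      A[g$bonds$a2[bb], g$bonds$a1[bb]] <- TRUE
    }
    diag(A) <- TRUE
    R <- A * 1
    for (step in seq_len(n)) {
      R2 <- (R %*% R > 0) * 1
      if (identical(R2, R)) break
      R <- R2
    }
    R <- R > 0
    ends <- c(g$bonds$a1[b], g$bonds$a2[b])
    for (k in 1:2) {
      side <- which(R[ends[k], ])
      heavy <- sum(!g$atoms$element[side] %in% c("H", "*"))
      if (heavy < 1 || heavy > max_heavy) next
      frag <- substispace:::.fragment_graph(g, side, ends[k])
      smi <- write_smiles(frag$graph, root = frag$star, digit_base = 2L)
      out[[length(out) + 1L]] <- data.frame(
        source_id = source_id, smiles = smi,
        att = attachment_category(
          g$atoms$element[ends[3 - k]],
          g$atoms$aromatic[ends[3 - k]],
          substispace:::is_carbonyl_carbon(g, ends[3 - k])))
    }
  }
  if (!length(out))
    return(data.frame(source_id = character(0), smiles = character(0),
                      att = character(0)))
  df <- do.call(rbind, out)
  df$smiles <- canonical_smiles(df$smiles)
  df
}

# multiset equality helper
expect_same_multiset <- function(a, b) {
  expect_equal(sort(a), sort(b))
}
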