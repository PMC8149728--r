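# Shared fixture builders. Everything is constructed in code; no files ship
# with the tests beyond what these helpers write to tempdir().

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

edges_df <- function(source, target, sign) {
  data.frame(source = source, target = target, sign = as.integer(sign),
             stringsAsFactors = FALSE)
}

# A tiny linear world: R -(+)-> I -(s2)-> T, with a regulon on T.
chain_network <- function(s1 = 1L, s2 = 1L) {
  signaling_network(edges_df(c("R", "I"), c("I", "T"), c(s1, s2)))
}

# Dense matrix -> validated sparse cells x genes matrix with generated names.
counts_matrix <- function(m, cells = NULL, genes = NULL) {
  m <- as.matrix(m)
  rownames(m) <- cells %||% sprintf("c%02d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  expression_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Profile built directly from a counts matrix treating all cells as one
# population.
one_pop_profile <- function(counts, pop = "p") {
  ann <- data.frame(cell = rownames(counts), population = pop,
                    stringsAsFactors = FALSE)
  profile_population(counts, ann, pop)
}

# Random signed digraph on n nodes for property tests. Returns a
# signaling_network; guarantees at least one edge.
random_network <- function(n, p_edge = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n))
  grid <- expand.grid(source = nodes, target = nodes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  keep <- stats::runif(nrow(grid)) < p_edge
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  e <- grid[keep, , drop = FALSE]
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  signaling_network(e)
}

# Forge a hotspot_set without running the Markov stage.
forged_hotspots <- function(intermediates) {
  structure(list(intermediates = intermediates, quantile_cut = NA_real_,
                 pi = NULL), class = "hotspot_set")
}

# Micro-world for the functional-receptor co-expression rule: 100 receiver
# cells; receptor "R", interface TF "T" with a balanced 10-target regulon
# whose 5 activated targets are population-active; exactly `n_joint` cells
# co-express R, T, and an active target.
cofrac_world <- function(n_joint, n_cells = 100L) {
  genes <- c("R", "I", "T", sprintf("P%d", 1:5), sprintf("Q%d", 1:5))
  m <- matrix(0, nrow = n_cells, ncol = length(genes),
              dimnames = list(sprintf("c%03d", seq_len(n_cells)), genes))
  m[, "I"] <- 1                      # intermediate active everywhere
  m[, sprintf("P%d", 1:5)] <- 1      # activated targets population-active
  m[1:60, "T"] <- 1                  # TF active in a majority
  m[seq_len(n_joint), "R"] <- 1      # joint cells: R & T & targets
  counts <- counts_matrix(m, genes = genes)
  regulon <- data.frame(target = c(sprintf("P%d", 1:5), sprintf("Q%d", 1:5)),
                        sign = rep(c(1L, -1L), each = 5),
                        stringsAsFactors = FALSE)
  network <- chain_network()
  profile <- one_pop_profile(counts)
  compat <- population_compatibility(network, forged_hotspots("I"), "T",
                                     list(T = regulon), profile)
  list(network = network, counts = counts, profile = profile,
       regulon = regulon, compat = compat)
}

# Full planted pipeline run for one seed; returns the interaction table.
planted_run <- function(seed, permute = FALSE) {
  sc <- planted_scenario(seed)
  kn <- generate_knowledge(sc)
  sim <- simulate_counts(sc, kn)
  ann <- sim$annotation
  if (permute) {
    ann$population <- intercom:::with_seed(seed * 1000L + 17L,
                                           sample(ann$population))
  }
  suppressWarnings(run_intercom(sim$counts, ann, kn$kb))
}

planted_row <- function(tab) {
  tab[tab$sender == "sender" & tab$receiver == "receiver" &
        tab$ligand == "Lig01" & tab$receptor == "Rcp01", , drop = FALSE]
}
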