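# Seeded synthetic world: random prior-knowledge tables plus a multi-
# population count matrix carrying a planted ligand -> receptor -> cascade ->
# TF -> target signal, so the whole pipeline is exercisable offline.
#
# The emulated regime is shallow plate-based single-cell data: sparse
# negative-binomial background counts with per-gene dropout (expressed
# fractions ~0.1-0.3), and a planted axis elevated to a ~0.65 expressed
# fraction (>= 3-fold over background) with visibly higher counts.

#' Construct a planted cell-cell communication scenario
#'
#' Fixes the sizes, names, and noise levels of the synthetic world. The
#' planted chain is `Lig01 -> Rcp01 -> Sig01 -> Sig02 -> Tf01` with
#' all-positive signs, and `Tf01`'s regulon contains at least five positively
#' regulated targets; the sender elevates the ligand, the receiver elevates
#' the receptor, cascade, TF, and the TF's positive targets, and the
#' bystander stays at background.
#'
#' @param seed integer seed driving every random draw.
#' @param n_cells cells per population, default 200.
#' @param n_genes total gene universe (network genes plus filler), default 300.
#' @param n_receptors,n_intermediates,n_tfs,n_targets_per_tf network sizes
#'   (defaults 8, 20, 8, 10).
#' @param edge_density probability of each random cross edge, default 0.15.
#' @param effect_fraction expressed fraction of planted genes in their
#'   elevated population, default 0.65 (>= 3-fold over the ~0.1-0.2
#'   background).
#' @param bg_mu,bg_size negative-binomial background (mean 0.3, dispersion 2).
#' @param planted_mu negative-binomial mean of the elevated counts, default 3.
#' @return named list of class `planted_scenario`.
#' @export
planted_scenario <- function(seed, n_cells = 200L, n_genes = 300L,
                             n_receptors = 8L, n_intermediates = 20L,
                             n_tfs = 8L, n_targets_per_tf = 10L,
                             edge_density = 0.15, effect_fraction = 0.65,
                             bg_mu = 0.3, bg_size = 2, planted_mu = 3) {
  stopifnot(n_receptors >= 1, n_intermediates >= 2, n_tfs >= 1,
            n_targets_per_tf >= 5, effect_fraction > 0, effect_fraction <= 1)
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_receptors = as.integer(n_receptors),
                 n_intermediates = as.integer(n_intermediates),
                 n_tfs = as.integer(n_tfs),
                 n_targets_per_tf = as.integer(n_targets_per_tf),
                 edge_density = edge_density,
                 effect_fraction = effect_fraction,
                 bg_mu = bg_mu, bg_size = bg_size, planted_mu = planted_mu,
                 populations = c("sender", "receiver", "bystander"),
                 ligand = "Lig01", receptor = "Rcp01",
                 cascade = c("Sig01", "Sig02"), tf = "Tf01"),
            class = "planted_scenario")
}

gene_names <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

#' Generate the synthetic prior-knowledge tables
#'
#' Draws a layered signed signaling network (receptors -> intermediates ->
#' TFs with random cross edges among intermediates), random +1/-1 regulons,
#' and a secreted-ligand scaffold. The planted chain and the planted TF's
#' positively regulated targets are inserted deterministically, so every draw
#' contains a recoverable signal. Fully reproducible per seed.
#'
#' @param scenario a `planted_scenario` (or a bare seed, promoted with
#'   defaults).
#' @return list with `scaffold` (data.frame), `signaling`
#'   (`signaling_network`), `regulons` (named list), and `kb`
#'   (assembled `knowledge_base`).
#' @export
generate_knowledge <- function(scenario) {
  if (is.numeric(scenario)) scenario <- planted_scenario(scenario)
  stopifnot(inherits(scenario, "planted_scenario"))
  sc <- scenario
  with_seed(sc$seed * 7L + 1L, {
    receptors <- gene_names("Rcp", sc$n_receptors)
    interms <- gene_names("Sig", sc$n_intermediates)
    tfs <- gene_names("Tf", sc$n_tfs)

    # Degree-regular layered topology: every intermediate and TF receives the
    # same number of incoming edges, so stationary-probability differences
    # reflect expression weights rather than in-degree hubs. The planted
    # chain replaces one random in-edge of each of its targets.
    in_deg <- max(2L, as.integer(round(sc$edge_density * 20)))
    planted <- data.frame(
      source = c(sc$receptor, sc$cascade[1], sc$cascade[2]),
      target = c(sc$cascade[1], sc$cascade[2], sc$tf),
      sign = 1L, stringsAsFactors = FALSE)
    pool_im <- c(receptors, interms)
    edges <- planted
    for (t in c(interms, tfs)) {
      pool <- if (t %in% tfs) interms else pool_im
      planted_src <- planted$source[planted$target == t]
      k <- in_deg - length(planted_src)
      avail <- setdiff(pool, c(t, planted_src))
      src <- sample(avail, min(k, length(avail)))
      if (length(src)) {
        edges <- rbind(edges, data.frame(
          source = src, target = t,
          sign = sample(c(-1L, 1L), length(src), replace = TRUE),
          stringsAsFactors = FALSE))
      }
    }
    # every receptor must feed the network somewhere
    for (r in setdiff(receptors, edges$source)) {
      edges <- rbind(edges, data.frame(source = r, target = sample(interms, 1),
                                       sign = sample(c(-1L, 1L), 1),
                                       stringsAsFactors = FALSE))
    }
    edges <- edges[!duplicated(paste(edges$source, edges$target)), , drop = FALSE]
    rownames(edges) <- NULL
    signaling <- signaling_network(edges)

    # regulons: disjoint target pools, random signs; planted TF gets >= 5
    # positive targets so a positive cascade predicts a testable active set
    regulons <- list()
    tg_idx <- 0L
    for (tf in tfs) {
      tg <- sprintf("Tg%03d", tg_idx + seq_len(sc$n_targets_per_tf))
      tg_idx <- tg_idx + sc$n_targets_per_tf
      sign <- sample(c(-1L, 1L), sc$n_targets_per_tf, replace = TRUE)
      if (tf == sc$tf) {
        # balanced planted regulon: 5 activated + >= 5 repressed targets, so
        # the planted-path agreement has deterministic power
        # (p = 1 / choose(10, 5) ~= 0.004 < alpha)
        sign <- rep(-1L, sc$n_targets_per_tf)
        sign[seq_len(5)] <- 1L
      }
      regulons[[tf]] <- data.frame(target = tg, sign = sign,
                                   stringsAsFactors = FALSE)
    }

    # scaffold: one dedicated secreted ligand per receptor plus extra pairs
    ligands <- gene_names("Lig", sc$n_receptors)
    scaffold <- data.frame(ligand = ligands, receptor = receptors,
                           secreted = TRUE, stringsAsFactors = FALSE)
    n_extra <- max(0L, 15L - nrow(scaffold))
    if (n_extra > 0) {
      extra <- data.frame(
        ligand = gene_names("Xlg", n_extra),
        receptor = sample(receptors, n_extra, replace = TRUE),
        secreted = TRUE, stringsAsFactors = FALSE)
      scaffold <- rbind(scaffold, extra)
    }

    list(scaffold = scaffold, signaling = signaling, regulons = regulons,
         kb = knowledge_base(scaffold, signaling, regulons))
  })
}

#' Simulate counts for a planted scenario
#'
#' Background counts are negative binomial (`bg_mu`, `bg_size`) thinned by a
#' per-gene dropout keep-probability ~ U(0.5, 1), yielding expressed
#' fractions of roughly 0.1-0.2. Planted genes are elevated in their
#' designated population to an expressed fraction of `effect_fraction`, with
#' expressing cells drawing `1 + NB(planted_mu, bg_size)` counts. All three
#' populations share the gene universe; the bystander is pure background.
#'
#' @param scenario a `planted_scenario`.
#' @param knowledge optional output of [generate_knowledge()] for the same
#'   scenario (regenerated when missing).
#' @return list with `counts` (cells x genes sparse matrix), `annotation`
#'   (data.frame `cell`, `population`), and `scenario`.
#' @export
simulate_counts <- function(scenario, knowledge = NULL) {
  if (is.numeric(scenario)) scenario <- planted_scenario(scenario)
  stopifnot(inherits(scenario, "planted_scenario"))
  sc <- scenario
  if (is.null(knowledge)) knowledge <- generate_knowledge(sc)
  kb_genes <- sort(unique(c(knowledge$scaffold$ligand, knowledge$scaffold$receptor,
                            knowledge$signaling$nodes, names(knowledge$regulons),
                            unlist(lapply(knowledge$regulons, `[[`, "target"),
                                   use.names = FALSE))))
  n_fill <- max(0L, sc$n_genes - length(kb_genes))
  genes <- c(kb_genes, sprintf("Bgr%03d", seq_len(n_fill)))

  planted_tf_targets <- knowledge$regulons[[sc$tf]]
  pos_targets <- planted_tf_targets$target[planted_tf_targets$sign == 1L]
  elevated <- list(
    sender = sc$ligand,
    receiver = c(sc$receptor, sc$cascade, sc$tf, pos_targets),
    bystander = character(0)
  )

  with_seed(sc$seed * 7L + 2L, {
    n_pop <- length(sc$populations)
    n_total <- sc$n_cells * n_pop
    keep_p <- stats::runif(length(genes), 0.5, 1)  # per-gene dropout
    names(keep_p) <- genes
    mats <- list()
    for (p in sc$populations) {
      m <- matrix(stats::rnbinom(sc$n_cells * length(genes),
                                 mu = sc$bg_mu, size = sc$bg_size),
                  nrow = sc$n_cells)
      drop <- matrix(stats::runif(length(m)) > rep(keep_p, each = sc$n_cells),
                     nrow = sc$n_cells)
      m[drop] <- 0L
      colnames(m) <- genes
      for (g in elevated[[p]]) {
        on <- stats::runif(sc$n_cells) < sc$effect_fraction
        cnt <- 1L + stats::rnbinom(sc$n_cells, mu = sc$planted_mu, size = sc$bg_size)
        m[, g] <- ifelse(on, cnt, 0L)
      }
      rownames(m) <- sprintf("%s_c%03d", p, seq_len(sc$n_cells))
      mats[[p]] <- m
    }
    counts <- do.call(rbind, mats)
    annotation <- data.frame(
      cell = rownames(counts),
      population = rep(sc$populations, each = sc$n_cells),
      stringsAsFactors = FALSE)
    list(counts = expression_matrix(counts), annotation = annotation,
         scenario = sc)
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the MatrixMarket count triplet, the annotation table, the three
#' prior-knowledge tables, and a scenario manifest, ready for the `run`
#' command.
#'
#' @param scenario a `planted_scenario` or bare seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_fixture <- function(scenario, dir) {
  if (is.numeric(scenario)) scenario <- planted_scenario(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  knowledge <- generate_knowledge(scenario)
  sim <- simulate_counts(scenario, knowledge)

  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    barcodes = file.path(dir, "barcodes.tsv"),
    features = file.path(dir, "features.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    lr = file.path(dir, "lr_scaffold.tsv"),
    signaling = file.path(dir, "signaling.tsv"),
    grn = file.path(dir, "regulons.tsv"),
    manifest = file.path(dir, "scenario.yaml")
  )
  Matrix::writeMM(Matrix::t(sim$counts), paths[["matrix"]])  # genes x cells
  writeLines(rownames(sim$counts), paths[["barcodes"]])
  writeLines(colnames(sim$counts), paths[["features"]])
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc_out <- knowledge$scaffold
  sc_out$secreted <- as.integer(sc_out$secreted)
  utils::write.table(sc_out, paths[["lr"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(knowledge$signaling$edges, paths[["signaling"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg <- do.call(rbind, lapply(names(knowledge$regulons), function(tf) {
    data.frame(tf = tf, target = knowledge$regulons[[tf]]$target,
               sign = knowledge$regulons[[tf]]$sign, stringsAsFactors = FALSE)
  }))
  utils::write.table(reg, paths[["grn"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(scenario), paths[["manifest"]])
  invisible(paths)
}
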