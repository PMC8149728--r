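# Interaction establishment, abundance scoring, top-decile significance, and
# the end-to-end pipeline driver.

#' Pipeline parameters
#'
#' Collects every tunable with its default. Fractions live in `[0, 1]`,
#' `alpha` in `(0, 1)`. The effective parameter set is echoed into the run
#' manifest and attached to the result table.
#'
#' @param tf_percentile preserved-TF cut (see [preserved_tfs()]), default 0.95.
#' @param tf_mode `"distribution"` or `"absolute"`.
#' @param hotspot_quantile stationary-probability cut, default 0.90.
#' @param damping Markov restart probability, default 0 (automatic fallback
#'   to 0.05 with a warning if power iteration fails to converge).
#' @param weight_mode `"fraction"` or `"mean"` (see [node_weights()]).
#' @param alpha compatibility significance level, default 0.05.
#' @param max_path_len signed-path length bound, default 5 edges.
#' @param min_cofrac joint co-expression floor for functional receptors
#'   (inclusive), default 0.05.
#' @param min_ligand_frac ligand expressed-fraction floor (strict), default 0.05.
#' @param score_quantile significance decile cut, default 0.90.
#' @param null_set `"scaffold"` (all scoreable scaffold pairs form the null)
#'   or `"candidates"`.
#' @param min_cells population size floor for a warning, default 20.
#' @param seed integer recorded in metadata (the pipeline itself is
#'   deterministic).
#' @return named list of class `intercom_params`.
#' @export
intercom_params <- function(tf_percentile = 0.95, tf_mode = "distribution",
                            hotspot_quantile = 0.90, damping = 0,
                            weight_mode = "fraction", alpha = 0.05,
                            max_path_len = 5L, min_cofrac = 0.05,
                            min_ligand_frac = 0.05, score_quantile = 0.90,
                            null_set = "scaffold", min_cells = 20L,
                            seed = NA_integer_) {
  p <- list(tf_percentile = tf_percentile, tf_mode = tf_mode,
            hotspot_quantile = hotspot_quantile, damping = damping,
            weight_mode = weight_mode, alpha = alpha,
            max_path_len = as.integer(max_path_len), min_cofrac = min_cofrac,
            min_ligand_frac = min_ligand_frac, score_quantile = score_quantile,
            null_set = null_set, min_cells = as.integer(min_cells), seed = seed)
  fracs <- c("tf_percentile", "hotspot_quantile", "min_cofrac",
             "min_ligand_frac", "score_quantile", "damping")
  for (f in fracs) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      abort_validation("parameter %s must be a fraction in [0, 1]", f)
    }
  }
  if (p$alpha <= 0 || p$alpha >= 1) abort_validation("alpha must be in (0, 1)")
  if (!p$tf_mode %in% c("distribution", "absolute")) abort_validation("bad tf_mode")
  if (!p$weight_mode %in% c("fraction", "mean")) abort_validation("bad weight_mode")
  if (!p$null_set %in% c("scaffold", "candidates")) abort_validation("bad null_set")
  structure(p, class = "intercom_params")
}

#' Candidate ligand-receptor interactions between two populations
#'
#' A scaffold pair is a candidate when the receptor is functional in the
#' receiver and the ligand is expressed in strictly more than
#' `min_ligand_frac` of the sender's cells.
#'
#' @param scaffold scaffold data.frame (`ligand`, `receptor`).
#' @param sender_profile the sender's `population_profile`.
#' @param functional character vector of the receiver's functional receptors.
#' @param min_ligand_frac strict lower bound on ligand fraction, default 0.05.
#' @return data.frame of candidate rows (`ligand`, `receptor`,
#'   `ligand_fraction`).
#' @export
candidate_interactions <- function(scaffold, sender_profile, functional,
                                   min_ligand_frac = 0.05) {
  frac <- stats::setNames(sender_profile$expressed_fraction, sender_profile$gene)
  lig_frac <- ifelse(scaffold$ligand %in% names(frac), frac[scaffold$ligand], 0)
  keep <- scaffold$receptor %in% functional & lig_frac > min_ligand_frac
  out <- data.frame(ligand = scaffold$ligand[keep],
                    receptor = scaffold$receptor[keep],
                    ligand_fraction = unname(lig_frac[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Abundance score of one ligand-receptor interaction
#'
#' The product of the sender's mean ligand expression over ligand-expressing
#' cells and the receiver's mean receptor expression over receptor-expressing
#' cells. Zero when either gene is unexpressed (or unmeasured).
#'
#' @param ligand,receptor gene symbols.
#' @param sender_profile,receiver_profile `population_profile` objects.
#' @return non-negative numeric score.
#' @export
interaction_score <- function(ligand, receptor, sender_profile, receiver_profile) {
  lm_ <- if (ligand %in% sender_profile$gene)
    sender_profile[ligand, "mean_expressing"] else 0
  rm_ <- if (receptor %in% receiver_profile$gene)
    receiver_profile[receptor, "mean_expressing"] else 0
  lm_ * rm_
}

#' Flag top-decile scores as significant
#'
#' A candidate score is significant when it is at least the `quantile`
#' (type 7) quantile of the reference score distribution — by default the
#' scores of all scaffold pairs scoreable between the two populations,
#' candidates and non-candidates alike.
#'
#' @param scores candidate scores.
#' @param reference reference score distribution (defaults to `scores`).
#' @param quantile cut, default 0.90.
#' @return logical vector along `scores`.
#' @export
flag_significant <- function(scores, reference = scores, quantile = 0.90) {
  if (length(scores) == 0L) return(logical(0))
  if (length(reference) == 0L) reference <- scores
  cut <- stats::quantile(reference, probs = quantile, type = 7, names = FALSE)
  scores >= cut
}

# Per-population upstream stages: profile -> preserved TFs -> hotspots ->
# compatibility -> functional receptors. Errors gain population context.
analyze_population <- function(pop, counts, annotation, kb, params) {
  withCallingHandlers(
    {
      profile <- profile_population(counts, annotation, pop)
      preserved <- preserved_tfs(profile, names(kb$regulons),
                                 percentile = params$tf_percentile,
                                 mode = params$tf_mode)
      itfs <- interface_tfs(kb$signaling, kb$regulons, preserved)
      w <- node_weights(profile, kb$signaling$nodes, mode = params$weight_mode)
      tm <- build_transition_matrix(kb$signaling, w, damping = params$damping)
      sd_ <- tryCatch(
        stationary_distribution(tm),
        intercom_convergence_error = function(e) {
          if (params$damping > 0) stop(e)
          warning(sprintf("population %s: chain did not converge at damping 0; retrying with damping 0.05", pop),
                  call. = FALSE)
          stationary_distribution(build_transition_matrix(kb$signaling, w, damping = 0.05))
        })
      # hotspots are ranked among intermediate molecules: regulon-bearing TFs
      # are dangling sinks whose stationary mass reflects topology, not
      # expression, and scaffold receptors are entry points, so both are
      # excluded from the quantile cut
      interm_nodes <- setdiff(kb$signaling$nodes,
                              c(names(kb$regulons), unique(kb$scaffold$receptor)))
      sd_hot <- if (length(interm_nodes) >= 2L) {
        structure(list(nodes = interm_nodes, pi = sd_$pi[interm_nodes],
                       iterations = sd_$iterations, residual = sd_$residual),
                  class = "stationary_distribution")
      } else sd_
      hot <- select_intermediates(sd_hot, quantile = params$hotspot_quantile)
      compat <- population_compatibility(kb$signaling, hot, itfs, kb$regulons,
                                         profile, alpha = params$alpha,
                                         max_path_len = params$max_path_len)
      cells <- annotation$cell[annotation$population == pop]
      fr <- functional_receptors(kb$signaling, hot, compat,
                                 receptors = unique(kb$scaffold$receptor),
                                 counts = counts[cells, , drop = FALSE],
                                 profile = profile, regulons = kb$regulons,
                                 min_cofrac = params$min_cofrac,
                                 max_path_len = params$max_path_len)
      list(profile = profile, preserved = preserved, interface_tfs = itfs,
           stationary = sd_, hotspots = hot, compatibility = compat,
           functional = fr)
    },
    error = function(e) {
      if (inherits(e, "intercom_error") && is.null(attr(e, "population"))) {
        e$message <- sprintf("[population %s] %s", pop, conditionMessage(e))
        attr(e, "population") <- pop
        stop(e)
      }
    })
}

#' Run the full interaction-inference pipeline
#'
#' Restricts the knowledge base to the measured genes, runs the per-
#' population stages (profiles, preserved TFs, signaling hotspots,
#' compatibility, functional receptors), then establishes, scores, and flags
#' interactions for every ordered population pair including self-pairs
#' (autocrine signaling). Deterministic given inputs and parameters.
#'
#' @param counts cells x genes matrix from [expression_matrix()] /
#'   [load_counts()].
#' @param annotation data.frame with `cell`, `population`.
#' @param kb a `knowledge_base` (secreted-filtered scaffold).
#' @param params an `intercom_params` list.
#' @return data.frame of class `interaction_table`, sorted by
#'   (sender, receiver, score descending, ligand, receptor), with columns
#'   `sender`, `receiver`, `ligand`, `receptor`, `ligand_fraction`,
#'   `receptor_fraction`, `score`, `significant`; per-population details are
#'   attached as attribute `details`, the parameters as attribute `params`.
#' @export
run_intercom <- function(counts, annotation, kb, params = intercom_params()) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(params, "intercom_params"))
  counts <- expression_matrix(counts)
  if (!all(annotation$cell %in% rownames(counts))) {
    abort_validation("annotation names cells absent from the matrix")
  }
  if (any(!colSums_nonint(counts))) {
    warning("non-integer values detected; the count >= 1 expression rule is applied as-is",
            call. = FALSE)
  }
  kb <- restrict_to_universe(kb, colnames(counts))
  sizes <- table(annotation$population)
  small <- names(sizes)[sizes < params$min_cells]
  if (length(small)) {
    warning(sprintf("population(s) below %d cells: %s", params$min_cells,
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  pops <- sort(unique(annotation$population))
  details <- lapply(pops, analyze_population, counts = counts,
                    annotation = annotation, kb = kb, params = params)
  names(details) <- pops

  rows <- list()
  for (sender in pops) {
    sp <- details[[sender]]$profile
    for (receiver in pops) {
      rp <- details[[receiver]]$profile
      functional <- details[[receiver]]$functional$receptors
      cand <- candidate_interactions(kb$scaffold, sp, functional,
                                     min_ligand_frac = params$min_ligand_frac)
      if (nrow(cand) == 0L) next
      cand$score <- vapply(seq_len(nrow(cand)), function(i) {
        interaction_score(cand$ligand[i], cand$receptor[i], sp, rp)
      }, numeric(1))
      reference <- if (params$null_set == "scaffold") {
        vapply(seq_len(nrow(kb$scaffold)), function(i) {
          interaction_score(kb$scaffold$ligand[i], kb$scaffold$receptor[i], sp, rp)
        }, numeric(1))
      } else {
        cand$score
      }
      cand$significant <- flag_significant(cand$score, reference,
                                           quantile = params$score_quantile)
      cand$receptor_fraction <- rp[cand$receptor, "expressed_fraction"]
      cand$sender <- sender
      cand$receiver <- receiver
      rows[[length(rows) + 1L]] <- cand
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ligand = character(0), receptor = character(0),
               ligand_fraction = numeric(0), score = numeric(0),
               significant = logical(0), receptor_fraction = numeric(0),
               sender = character(0), receiver = character(0),
               stringsAsFactors = FALSE)
  out <- out[c("sender", "receiver", "ligand", "receptor", "ligand_fraction",
               "receptor_fraction", "score", "significant")]
  ord <- order(out$sender, out$receiver, -out$score, out$ligand, out$receptor)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = params, details = details,
            class = c("interaction_table", "data.frame"))
}

# TRUE per column when all stored values are integer-valued.
colSums_nonint <- function(m) {
  x <- m@x
  length(x) == 0L || all(x == floor(x))
}

#' Reshape an interaction table into a heatmap-ready wide matrix
#'
#' Rows are `LIGAND-RECEPTOR` labels, columns `sender-receiver` population
#' pairs, values the abundance score (NA where the pair was not established).
#'
#' @param tab an `interaction_table`.
#' @return numeric matrix.
#' @export
interaction_heatmap_matrix <- function(tab) {
  if (nrow(tab) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  rlab <- paste(tab$ligand, tab$receptor, sep = "-")
  clab <- paste(tab$sender, tab$receiver, sep = "-")
  m <- matrix(NA_real_, nrow = length(unique(rlab)), ncol = length(unique(clab)),
              dimnames = list(unique(rlab), unique(clab)))
  for (i in seq_len(nrow(tab))) m[rlab[i], clab[i]] <- tab$score[i]
  m
}
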