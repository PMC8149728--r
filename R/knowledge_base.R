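# Prior-knowledge inputs: ligand-receptor scaffold, signed signaling network,
# signed regulons. All gene identifiers are case-sensitive symbols matched by
# strict string equality against the expression matrix gene names.

#' Load a ligand-receptor scaffold
#'
#' Reads a tab-delimited table with columns `ligand` and `receptor` and an
#' optional `secreted` column (`0/1/true/false`). Duplicate (ligand, receptor)
#' pairs are collapsed to one row. When `secreted` is absent, every ligand is
#' assumed secreted and a warning is emitted, so pre-curated scaffolds are not
#' blocked.
#'
#' @param path path to a tab-delimited file with a header row; lines starting
#'   with `#` are skipped.
#' @return data.frame with columns `ligand`, `receptor`, `secreted` (logical).
#' @export
load_lr_scaffold <- function(path) {
  df <- read_tsv_checked(path, c("ligand", "receptor"), "ligand-receptor scaffold")
  if (nrow(df) == 0L) abort_validation("ligand-receptor scaffold is empty: %s", path)
  if (!"secreted" %in% names(df)) {
    warning("scaffold has no 'secreted' column; assuming all ligands secreted",
            call. = FALSE)
    df$secreted <- TRUE
  }
  secreted <- tolower(trimws(as.character(df$secreted))) %in% c("1", "true", "t", "yes")
  out <- data.frame(ligand = as.character(df$ligand),
                    receptor = as.character(df$receptor),
                    secreted = secreted,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out[c("ligand", "receptor")])
  if (any(dup)) {
    log_msg(sum(dup), " duplicate ligand-receptor pair(s) collapsed")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Keep only pairs with a secreted ligand
#'
#' The pipeline is restricted by design to paracrine/autocrine signaling, so
#' membrane-bound (juxtacrine) ligands are removed up front. Row order is
#' preserved.
#'
#' @param pairs scaffold data.frame from [load_lr_scaffold()].
#' @return filtered scaffold data.frame.
#' @export
filter_secreted <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("ligand", "receptor", "secreted") %in% names(pairs)))
  out <- pairs[isTRUE_vec(pairs$secreted), , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) as.logical(x) %in% TRUE

# Collapse duplicate signed edges; drop (source, target) pairs whose duplicate
# rows carry opposite signs (ambiguous evidence -> no known effect).
resolve_sign_conflicts <- function(edges, what) {
  key <- paste(edges$source, edges$target, sep = "\r")
  nsign <- vapply(split(edges$sign, key), function(s) length(unique(s)), integer(1))
  conflicted <- names(nsign)[nsign > 1L]
  if (length(conflicted)) {
    log_msg(length(conflicted), " ", what,
            " edge(s) dropped due to conflicting signs")
    warning(sprintf("%d %s edge(s) with conflicting signs dropped", length(conflicted), what),
            call. = FALSE)
    edges <- edges[!key %in% conflicted, , drop = FALSE]
    key <- paste(edges$source, edges$target, sep = "\r")
  }
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Build a signaling network object from a signed edge table
#'
#' @param edges data.frame with character columns `source`, `target` and an
#'   integer `sign` column restricted to `+1`/`-1`.
#' @return object of class `signaling_network`: a list with `nodes` (sorted
#'   union of edge endpoints) and `edges`.
#' @export
signaling_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("source", "target", "sign") %in% names(edges)))
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L))) {
    abort_validation("signaling edge signs must be +1 or -1")
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges), class = "signaling_network")
}

#' Load a signed intracellular signaling network
#'
#' Reads a tab-delimited table with columns `source`, `target`, `sign`. Sign
#' vocabulary: `1`, `+1`, `-1`, `activation`, `inhibition`. Self-loops are
#' dropped with a warning; exact duplicate edges are collapsed; duplicates
#' with opposite signs are dropped entirely (the effect is not known).
#'
#' @inheritParams load_lr_scaffold
#' @return a `signaling_network` object.
#' @export
load_signaling_network <- function(path) {
  df <- read_tsv_checked(path, c("source", "target", "sign"), "signaling network")
  sign <- parse_sign(df$sign)
  if (anyNA(sign)) {
    bad <- unique(as.character(df$sign)[is.na(sign)])
    abort_format("unrecognized sign value(s) in signaling network: %s",
                 paste(bad, collapse = ", "))
  }
  edges <- data.frame(source = as.character(df$source),
                      target = as.character(df$target),
                      sign = sign, stringsAsFactors = FALSE)
  self <- edges$source == edges$target
  if (any(self)) {
    warning(sprintf("%d self-loop(s) dropped from signaling network", sum(self)),
            call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  edges <- resolve_sign_conflicts(edges, "signaling")
  signaling_network(edges)
}

#' Load signed transcriptional regulons
#'
#' Reads a tab-delimited table with columns `tf`, `target`, `sign`, keeping
#' only direct regulations with a known effect. Rows whose sign cannot be
#' parsed to +1/-1 (including 0/blank) are rejected with a counted warning;
#' duplicate (tf, target) rows with conflicting signs are dropped.
#'
#' @inheritParams load_lr_scaffold
#' @return named list mapping TF symbol to a data.frame with columns `target`
#'   and `sign`.
#' @export
load_regulons <- function(path) {
  df <- read_tsv_checked(path, c("tf", "target", "sign"), "regulon")
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  sign <- parse_sign(df$sign)
  if (anyNA(sign)) {
    warning(sprintf("%d regulon row(s) rejected (sign missing, zero, or unparseable)",
                    sum(is.na(sign))), call. = FALSE)
    df <- df[!is.na(sign), , drop = FALSE]
    sign <- sign[!is.na(sign)]
  }
  edges <- data.frame(source = as.character(df$tf),
                      target = as.character(df$target),
                      sign = sign, stringsAsFactors = FALSE)
  edges <- resolve_sign_conflicts(edges, "regulatory")
  split_df <- split(edges[c("target", "sign")], edges$source)
  lapply(split_df, function(d) {
    rownames(d) <- NULL
    d
  })
}

#' Assemble a prior-knowledge container
#'
#' Bundles the secreted-ligand scaffold, the signed signaling network, and the
#' regulons, and computes node roles: a node is a receptor if it appears as a
#' scaffold receptor, and an interface TF if it owns a regulon and has at
#' least one incoming signaling edge (the first transcription factor reachable
#' along a transduction chain).
#'
#' @param scaffold data.frame from [load_lr_scaffold()] (after
#'   [filter_secreted()] if desired).
#' @param signaling a `signaling_network`.
#' @param regulons named list from [load_regulons()].
#' @return object of class `knowledge_base`.
#' @export
knowledge_base <- function(scaffold, signaling, regulons) {
  stopifnot(is.data.frame(scaffold), inherits(signaling, "signaling_network"),
            is.list(regulons))
  kb <- structure(list(scaffold = scaffold, signaling = signaling,
                       regulons = regulons, roles = NULL),
                  class = "knowledge_base")
  kb$roles <- compute_roles(kb)
  kb
}

compute_roles <- function(kb) {
  nodes <- kb$signaling$nodes
  has_regulon <- nodes %in% names(kb$regulons)
  has_incoming <- nodes %in% kb$signaling$edges$target
  data.frame(
    node = nodes,
    is_receptor = nodes %in% kb$scaffold$receptor,
    is_interface_tf = has_regulon & has_incoming,
    stringsAsFactors = FALSE
  )
}

#' Restrict a knowledge base to the measured gene universe
#'
#' Removes every scaffold pair, signaling edge, and regulon entry that
#' mentions a gene absent from `genes`, recomputes node role flags, and logs
#' removal counts. Idempotent.
#'
#' @param kb a `knowledge_base`.
#' @param genes character vector of measured gene symbols.
#' @return restricted `knowledge_base`.
#' @export
restrict_to_universe <- function(kb, genes) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (length(genes) == 0L) abort_validation("gene universe is empty")
  genes <- unique(as.character(genes))

  sc <- kb$scaffold
  keep_sc <- sc$ligand %in% genes & sc$receptor %in% genes
  if (any(!keep_sc)) log_msg(sum(!keep_sc), " scaffold pair(s) removed (unmeasured gene)")
  sc <- sc[keep_sc, , drop = FALSE]
  rownames(sc) <- NULL
  if (nrow(sc) == 0L) {
    abort_validation("no ligand-receptor scaffold pair survives restriction to the measured genes")
  }

  ed <- kb$signaling$edges
  keep_ed <- ed$source %in% genes & ed$target %in% genes
  if (any(!keep_ed)) log_msg(sum(!keep_ed), " signaling edge(s) removed (unmeasured gene)")
  ed <- ed[keep_ed, , drop = FALSE]
  if (nrow(ed) == 0L) {
    abort_validation("no signaling edge survives restriction to the measured genes")
  }

  reg <- kb$regulons[names(kb$regulons) %in% genes]
  n_tf_dropped <- length(kb$regulons) - length(reg)
  n_tgt_dropped <- 0L
  reg <- lapply(reg, function(d) {
    keep <- d$target %in% genes
    n_tgt_dropped <<- n_tgt_dropped + sum(!keep)
    d2 <- d[keep, , drop = FALSE]
    rownames(d2) <- NULL
    d2
  })
  reg <- reg[vapply(reg, nrow, integer(1)) > 0L]
  if (n_tf_dropped || n_tgt_dropped) {
    log_msg(n_tf_dropped, " regulon(s) and ", n_tgt_dropped,
            " regulon target(s) removed (unmeasured gene)")
  }

  knowledge_base(sc, signaling_network(ed), reg)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("knowledge_base:",
      nrow(x$scaffold), "LR pairs;",
      length(x$signaling$nodes), "signaling nodes /",
      nrow(x$signaling$edges), "edges;",
      length(x$regulons), "regulons;",
      sum(x$roles$is_interface_tf), "interface TFs\n")
  invisible(x)
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("signaling_network:", length(x$nodes), "nodes,", nrow(x$edges), "signed edges\n")
  invisible(x)
}
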