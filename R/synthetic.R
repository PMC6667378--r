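#' @title Synthetic knowledge bases and the matching sensitivity experiment
#'
#' @description The generator emulates the structure of a curated reaction
#' database: hierarchical pathways containing reactions whose participants
#' are proteoforms with roles and complex/set context, a configurable
#' fraction of proteins carrying PTM-annotated proteoforms, a gene-name map,
#' a variant map and protein sequences. The sensitivity experiment perturbs
#' reference proteoforms (first PTM type replaced by the \code{00000}
#' wildcard, first and second PTM sites shifted by +5 residues) and measures,
#' per matching stringency, how often the perturbed proteoform still finds
#' its own original (sensitivity) and how often it hits other same-accession
#' proteoforms (the complement of specificity).
#'
#' @name synthetic
NULL

# PSI-MOD types sampled by the generator; includes the three phospho types
SYNTH_PTM_CATALOGUE <- c("00046", "00047", "00048", "00064", "00084",
                         "00085", "00087", "00134", "00798", "01148")

#' Generate a reproducible synthetic knowledge base
#'
#' @param n_proteins number of distinct protein accessions.
#' @param isoform_fraction fraction of proteins that also contribute a
#'   non-canonical isoform proteoform.
#' @param ptm_fraction fraction of proteins carrying PTM-annotated
#'   proteoforms (each such protein receives 1-3 modified forms).
#' @param max_ptms_per_proteoform maximum PTM count per modified proteoform.
#' @param n_reactions number of reactions.
#' @param participants_per_reaction integer range \code{c(min, max)} of
#'   participants per reaction.
#' @param n_pathways number of pathways.
#' @param hierarchy_depth maximum depth of the pathway parent hierarchy.
#' @param seed integer seed; fixed seed gives a byte-identical knowledge
#'   base on disk.
#' @return A \code{"knowledge_base"} object with gene map, variant map and
#'   sequences populated.
#' @details Synthetic protein sequences are 120-400 residues long and PTM
#'   sites are drawn in \code{[1, length - 10]} so that the +5 shift of the
#'   sensitivity experiment never leaves the sequence. Every proteoform
#'   participates in at least one reaction and every reaction belongs to at
#'   least one pathway.
#' @export
generate_synthetic_kb <- function(n_proteins = 500,
                                  isoform_fraction = 0.1,
                                  ptm_fraction = 0.6,
                                  max_ptms_per_proteoform = 3,
                                  n_reactions = 400,
                                  participants_per_reaction = c(2L, 6L),
                                  n_pathways = 60,
                                  hierarchy_depth = 3,
                                  seed = 1L) {
  cfg_err <- function(...) stop(condition_error(...,
                                                class = "proteopath_config_error"))
  if (n_proteins < 1 || n_reactions < 1 || n_pathways < 1) {
    cfg_err("n_proteins, n_reactions and n_pathways must be positive")
  }
  if (ptm_fraction < 0 || ptm_fraction > 1 ||
      isoform_fraction < 0 || isoform_fraction > 1) {
    cfg_err("fractions must lie in [0, 1]")
  }
  if (max_ptms_per_proteoform < 1) cfg_err("max_ptms_per_proteoform must be >= 1")
  ppr <- as.integer(participants_per_reaction)
  if (length(ppr) != 2L || ppr[1] < 2L || ppr[2] < ppr[1]) {
    cfg_err("participants_per_reaction must be c(min, max) with min >= 2")
  }
  if (ppr[2] > n_proteins) {
    cfg_err("participants_per_reaction exceeds the number of proteins")
  }
  if (hierarchy_depth < 1) cfg_err("hierarchy_depth must be >= 1")

  set.seed(as.integer(seed))
  width <- max(5L, nchar(n_proteins))
  accs <- sprintf(paste0("SP%0", width, "d"), seq_len(n_proteins))
  genes <- sprintf(paste0("GENE%0", width, "d"), seq_len(n_proteins))
  seq_len_aa <- sample(120:400, n_proteins, replace = TRUE)
  sequences <- vapply(seq_len_aa, function(L) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                 replace = TRUE), collapse = "")
  }, character(1))
  names(sequences) <- accs

  # every protein contributes its unmodified canonical proteoform; a
  # ptm_fraction share additionally carries 1-3 modified forms, and an
  # isoform_fraction share an unmodified non-canonical isoform
  pfs <- lapply(accs, function(a) proteoform(a))
  modified <- accs[stats::runif(n_proteins) < ptm_fraction]
  for (a in modified) {
    n_forms <- sample(1:3, 1L)
    max_site <- max(1L, seq_len_aa[match(a, accs)] - 10L)
    for (f in seq_len(n_forms)) {
      n_ptms <- sample(seq_len(max_ptms_per_proteoform), 1L)
      types <- sample(SYNTH_PTM_CATALOGUE, n_ptms, replace = TRUE)
      sites <- sample(seq_len(max_site), n_ptms, replace = FALSE)
      pfs[[length(pfs) + 1L]] <- proteoform(a, NA, types, sites)
    }
  }
  with_isoform <- accs[stats::runif(n_proteins) < isoform_fraction]
  for (a in with_isoform) {
    pfs[[length(pfs) + 1L]] <- proteoform(a, 2L)
  }
  pf_str <- sort(unique(vapply(pfs, format_proteoform, character(1))))

  # reactions: sampled participant sets; then sweep so every proteoform
  # appears in at least one reaction
  rid <- sprintf("R%05d", seq_len(n_reactions))
  rname <- paste0("Reaction ", seq_len(n_reactions))
  rows <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    m <- sample(ppr[1]:ppr[2], 1L)
    members <- sample(pf_str, min(m, length(pf_str)))
    roles <- sample(PARTICIPANT_ROLES, length(members), replace = TRUE)
    ctx <- sample(c("individual", "complex", "set"), length(members),
                  replace = TRUE, prob = c(0.6, 0.3, 0.1))
    ctx[ctx == "complex"] <- paste0("complex:C", i)
    ctx[ctx == "set"] <- paste0("set:S", i)
    rows[[i]] <- data.frame(reaction_id = rid[i], reaction_name = rname[i],
                            proteoform = members, role = roles, context = ctx,
                            stringsAsFactors = FALSE)
  }
  participants <- do.call(rbind, rows)
  orphan <- setdiff(pf_str, participants$proteoform)
  if (length(orphan)) {
    host <- sample(rid, length(orphan), replace = TRUE)
    participants <- rbind(participants, data.frame(
      reaction_id = host,
      reaction_name = rname[match(host, rid)],
      proteoform = orphan,
      role = sample(PARTICIPANT_ROLES, length(orphan), replace = TRUE),
      context = "individual", stringsAsFactors = FALSE))
  }

  # pathway hierarchy: each non-root pathway picks a parent among earlier
  # pathways whose depth is below hierarchy_depth
  pid <- sprintf("PW%04d", seq_len(n_pathways))
  pname <- paste0("Pathway ", seq_len(n_pathways))
  parent <- rep(NA_character_, n_pathways)
  depth <- rep(1L, n_pathways)
  n_roots <- max(1L, ceiling(n_pathways / 6))
  if (n_pathways > n_roots) {
    for (i in (n_roots + 1L):n_pathways) {
      eligible <- which(depth[seq_len(i - 1L)] < hierarchy_depth)
      if (length(eligible) == 0L) next
      j <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      parent[i] <- pid[j]
      depth[i] <- depth[j] + 1L
    }
  }
  pathways <- data.frame(pathway_id = pid, pathway_name = pname,
                         parent_id = parent, stringsAsFactors = FALSE)
  # each reaction is assigned to one pathway; leaf-ward pathways preferred so
  # the hierarchy closure is informative
  assign_to <- sample(pid, n_reactions, replace = TRUE,
                      prob = depth / sum(depth))
  pathway_reactions <- data.frame(pathway_id = assign_to, reaction_id = rid,
                                  stringsAsFactors = FALSE)

  gene_map <- data.frame(gene_name = genes, accession = accs,
                         stringsAsFactors = FALSE)
  n_variants <- n_proteins
  variant_map <- data.frame(
    variant_id = paste0("rs", sprintf("%06d", seq_len(n_variants))),
    accession = sample(accs, n_variants, replace = TRUE),
    stringsAsFactors = FALSE)

  kb <- new_kb(proteoforms = pf_str, participants = participants,
               pathways = pathways, pathway_reactions = pathway_reactions,
               gene_map = gene_map, variant_map = variant_map,
               sequences = sequences)
  validate_kb(kb)
  kb
}

#' Perturb a proteoform for the sensitivity experiment
#'
#' The first PTM (in canonical serialization order) has its type replaced by
#' the \code{00000} wildcard and its site increased by 5 positions; if a
#' second PTM exists its site is increased by 5 as well. Remaining PTMs are
#' unchanged. Unknown sites stay unknown.
#'
#' @param p a \code{"proteoform"} with at least one PTM.
#' @return A list with elements \code{original} and \code{altered}.
#' @examples
#' rec <- alter_proteoform(parse_proteoform("X1;00046:15,00047:30"))
#' format_proteoform(rec$altered)  # "X1;00000:20,00047:35"
#' @export
alter_proteoform <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  if (ptm_count(p) == 0L) {
    stop(condition_error("cannot alter a proteoform without PTMs: ",
                         format_proteoform(p),
                         class = "proteopath_config_error"))
  }
  ptms <- p$ptms
  shift <- function(m) {
    if (!is.na(m$site)) m$site <- m$site + 5L
    m
  }
  ptms[[1]] <- shift(ptms[[1]])
  ptms[[1]]$type <- PTM_TYPE_WILDCARD
  if (length(ptms) >= 2L) ptms[[2]] <- shift(ptms[[2]])
  altered <- proteoform(p$accession, p$isoform,
                        vapply(ptms, `[[`, character(1), "type"),
                        vapply(ptms, `[[`, integer(1), "site"))
  list(original = p, altered = altered)
}

# reference proteoforms eligible for the experiment: modified proteoforms of
# proteins that have multiple proteoforms with at least one PTM
eligible_proteoforms <- function(kb) {
  pfs <- kb_parsed_proteoforms(kb)
  has_ptm <- vapply(pfs, function(p) ptm_count(p) > 0L, logical(1))
  accs <- vapply(pfs, `[[`, character(1), "accession")
  counts <- table(accs[has_ptm])
  multi <- names(counts)[counts >= 2L]
  which(has_ptm & accs %in% multi)
}

#' Matching sensitivity under proteoform perturbation
#'
#' Draws \code{n_samples} seeded samples of \code{sample_size} eligible
#' reference proteoforms (without replacement within a sample), perturbs each
#' with \code{\link{alter_proteoform}}, and matches the perturbed proteoforms
#' back against all same-accession reference proteoforms under each
#' requested matching configuration.
#'
#' @param kb a \code{"knowledge_base"}.
#' @param n_samples number of samples (default 10).
#' @param sample_size proteoforms per sample (default 300).
#' @param configs list of \code{\link{matching_config}} objects; default all
#'   eight matching types at margin 5.
#' @param seed integer seed.
#' @return A data.frame with one row per (matching type, sample):
#'   \code{matching_type}, \code{margin}, \code{sample},
#'   \code{original_pct} (share of perturbed proteoforms matching their own
#'   original, in percent) and \code{others_pct} (share matching at least one
#'   other same-accession proteoform).
#' @export
sensitivity_experiment <- function(kb, n_samples = 10L, sample_size = 300L,
                                   configs = NULL, seed = 1L) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (is.null(configs)) {
    configs <- lapply(MATCHING_TYPES, matching_config, margin = 5L)
  }
  idx <- eligible_proteoforms(kb)
  if (length(idx) < sample_size) {
    stop(condition_error("knowledge base has ", length(idx),
                         " eligible proteoforms; sample_size ", sample_size,
                         " requires at least that many",
                         class = "proteopath_config_error"))
  }
  pfs <- kb_parsed_proteoforms(kb)
  accs <- vapply(pfs, `[[`, character(1), "accession")
  by_acc <- split(seq_along(pfs), accs)
  set.seed(as.integer(seed))
  out <- list()
  for (s in seq_len(n_samples)) {
    chosen <- sample(idx, sample_size)
    recs <- lapply(pfs[chosen], alter_proteoform)
    for (cfg in configs) {
      hit_orig <- logical(sample_size)
      hit_other <- logical(sample_size)
      for (i in seq_len(sample_size)) {
        rec <- recs[[i]]
        cand <- by_acc[[rec$original$accession]]
        orig_str <- format_proteoform(rec$original)
        for (j in cand) {
          if (!match_proteoform(rec$altered, pfs[[j]], cfg)) next
          if (format_proteoform(pfs[[j]]) == orig_str) hit_orig[i] <- TRUE
          else hit_other[i] <- TRUE
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        matching_type = cfg$matching_type, margin = cfg$margin, sample = s,
        original_pct = 100 * mean(hit_orig),
        others_pct = 100 * mean(hit_other), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
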