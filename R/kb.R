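#' @title The pathway knowledge base
#'
#' @description A knowledge base holds hierarchical pathways containing
#' biochemical reactions whose participants are proteoforms with a role
#' (input, output, catalyst or regulator) and a complex/set context, plus
#' identifier maps: gene name to accession, optional variant identifier to
#' accession, and optional protein sequences. It is stored on disk as a
#' directory of five tab-separated files with a header row:
#' \itemize{
#'   \item \code{proteoforms.tsv}: column \code{proteoform} — every distinct
#'     reference proteoform in the notation of \code{\link{parse_proteoform}}.
#'   \item \code{genes.tsv}: \code{gene_name}, \code{accession}.
#'   \item \code{reactions.tsv}: \code{reaction_id}, \code{reaction_name},
#'     \code{proteoform}, \code{role}, \code{context} — one row per
#'     participant.
#'   \item \code{pathways.tsv}: \code{pathway_id}, \code{pathway_name},
#'     \code{parent_id} (\code{"-"} for a top-level pathway).
#'   \item \code{pathway_reactions.tsv}: \code{pathway_id}, \code{reaction_id}.
#' }
#' plus optionally \code{variants.tsv} (\code{variant_id}, \code{accession})
#' and \code{sequences.fasta}. Reference PTM sites given as the legacy
#' sentinel \code{-1} are normalized to unknown at load time.
#'
#' @name knowledge_base
NULL

PARTICIPANT_ROLES <- c("input", "output", "catalyst", "regulator")

KB_REQUIRED_FILES <- c("proteoforms.tsv", "genes.tsv", "reactions.tsv",
                       "pathways.tsv", "pathway_reactions.tsv")

read_kb_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character", sep = "\t",
                    quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

# parse + canonicalize a column of proteoform strings, reporting file/line
# on failure; '-1' reference sites are normalized to unknown first
canonicalize_proteoform_column <- function(strings, file) {
  vapply(seq_along(strings), function(i) {
    s <- gsub(":-1(?=[,;]|$)", ":?", strings[[i]], perl = TRUE)
    tryCatch(format_proteoform(parse_proteoform(s)), error = function(e) {
      stop(condition_error("malformed proteoform in ", file, " line ", i + 1L,
                           ": ", conditionMessage(e),
                           class = class(e)[1]))
    })
  }, character(1))
}

#' Load a knowledge base from a directory of flat files
#'
#' @param dir directory containing the five TSV files described in
#'   \link{knowledge_base}, plus optional \code{variants.tsv} and
#'   \code{sequences.fasta}.
#' @return A fully cross-referenced \code{"knowledge_base"} object.
#' @export
load_kb <- function(dir) {
  if (!dir.exists(dir)) {
    stop(condition_error("knowledge-base directory not found: ", dir,
                         class = "proteopath_config_error"))
  }
  missing <- KB_REQUIRED_FILES[!file.exists(file.path(dir, KB_REQUIRED_FILES))]
  if (length(missing)) {
    stop(condition_error("knowledge-base directory ", dir,
                         " is missing required file(s): ",
                         paste(missing, collapse = ", "),
                         class = "proteopath_config_error"))
  }
  proteoforms <- read_kb_tsv(file.path(dir, "proteoforms.tsv"))
  genes <- read_kb_tsv(file.path(dir, "genes.tsv"))
  reactions <- read_kb_tsv(file.path(dir, "reactions.tsv"))
  pathways <- read_kb_tsv(file.path(dir, "pathways.tsv"))
  pathway_reactions <- read_kb_tsv(file.path(dir, "pathway_reactions.tsv"))

  pf <- canonicalize_proteoform_column(proteoforms$proteoform,
                                       "proteoforms.tsv")
  reactions$proteoform <- canonicalize_proteoform_column(reactions$proteoform,
                                                         "reactions.tsv")
  pathways$parent_id[pathways$parent_id == "-"] <- NA_character_

  variant_map <- NULL
  if (file.exists(file.path(dir, "variants.tsv"))) {
    variant_map <- read_kb_tsv(file.path(dir, "variants.tsv"))
  }
  sequences <- NULL
  if (file.exists(file.path(dir, "sequences.fasta"))) {
    aa <- Biostrings::readAAStringSet(file.path(dir, "sequences.fasta"))
    sequences <- as.character(aa)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  kb <- new_kb(proteoforms = sort(unique(pf)),
               participants = reactions,
               pathways = pathways,
               pathway_reactions = pathway_reactions,
               gene_map = genes,
               variant_map = variant_map,
               sequences = sequences)
  validate_kb(kb)
  kb
}

new_kb <- function(proteoforms, participants, pathways, pathway_reactions,
                   gene_map, variant_map = NULL, sequences = NULL) {
  structure(list(proteoforms = proteoforms,
                 participants = participants,
                 pathways = pathways,
                 pathway_reactions = pathway_reactions,
                 gene_map = gene_map,
                 variant_map = variant_map,
                 sequences = sequences),
            class = "knowledge_base")
}

validate_kb <- function(kb) {
  integrity <- function(...) {
    stop(condition_error(..., class = "proteopath_integrity_error"))
  }
  prt <- kb$participants
  if (nrow(prt) == 0L) integrity("knowledge base has no reaction participants")
  bad_role <- setdiff(unique(prt$role), PARTICIPANT_ROLES)
  if (length(bad_role)) {
    integrity("unknown participant role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_ctx <- unique(prt$context[!grepl("^(individual|complex:.+|set:.+)$",
                                       prt$context)])
  if (length(bad_ctx)) {
    integrity("unknown participant context(s): ",
              paste(bad_ctx, collapse = ", "))
  }
  dangling_pf <- setdiff(unique(prt$proteoform), kb$proteoforms)
  if (length(dangling_pf)) {
    integrity("reaction participant proteoform(s) absent from ",
              "proteoforms.tsv: ", paste(dangling_pf, collapse = ", "))
  }
  rids <- unique(prt$reaction_id)
  dangling_r <- setdiff(unique(kb$pathway_reactions$reaction_id), rids)
  if (length(dangling_r)) {
    integrity("pathway_reactions.tsv references unknown reaction(s): ",
              paste(dangling_r, collapse = ", "))
  }
  pids <- kb$pathways$pathway_id
  if (anyDuplicated(pids)) {
    integrity("duplicated pathway identifier(s): ",
              paste(unique(pids[duplicated(pids)]), collapse = ", "))
  }
  dangling_p <- setdiff(unique(kb$pathway_reactions$pathway_id), pids)
  if (length(dangling_p)) {
    integrity("pathway_reactions.tsv references unknown pathway(s): ",
              paste(dangling_p, collapse = ", "))
  }
  dangling_parent <- setdiff(stats::na.omit(kb$pathways$parent_id), pids)
  if (length(dangling_parent)) {
    integrity("pathways.tsv references unknown parent pathway(s): ",
              paste(dangling_parent, collapse = ", "))
  }
  # parent links must be acyclic: follow each chain at most |pathways| steps
  parent_of <- stats::setNames(kb$pathways$parent_id, pids)
  for (p in pids) {
    cur <- p
    for (step in seq_len(length(pids) + 1L)) {
      cur <- parent_of[[cur]]
      if (is.na(cur)) break
      if (cur == p) integrity("pathway parent links form a cycle at: ", p)
    }
  }
  invisible(kb)
}

#' Write a knowledge base to a directory of flat files
#'
#' Inverse of \code{\link{load_kb}}; rows are emitted in a deterministic
#' sorted order so equal knowledge bases produce byte-identical files.
#'
#' @param kb a \code{"knowledge_base"}.
#' @param dir destination directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
save_kb <- function(kb, dir) {
  stopifnot(inherits(kb, "knowledge_base"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) {
    stop(condition_error("cannot create knowledge-base directory: ", dir,
                         class = "proteopath_config_error"))
  }
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(data.frame(proteoform = sort(unique(kb$proteoforms)),
                       stringsAsFactors = FALSE), "proteoforms.tsv")
  gm <- kb$gene_map[order(kb$gene_map$gene_name, kb$gene_map$accession), ,
                    drop = FALSE]
  write_tsv(gm, "genes.tsv")
  prt <- kb$participants
  prt <- prt[order(prt$reaction_id, prt$proteoform, prt$role, prt$context), ,
             drop = FALSE]
  write_tsv(prt, "reactions.tsv")
  pw <- kb$pathways
  pw$parent_id[is.na(pw$parent_id)] <- "-"
  pw <- pw[order(pw$pathway_id), , drop = FALSE]
  write_tsv(pw, "pathways.tsv")
  pr <- kb$pathway_reactions[order(kb$pathway_reactions$pathway_id,
                                   kb$pathway_reactions$reaction_id), ,
                             drop = FALSE]
  write_tsv(pr, "pathway_reactions.tsv")
  if (!is.null(kb$variant_map)) {
    vm <- kb$variant_map[order(kb$variant_map$variant_id,
                               kb$variant_map$accession), , drop = FALSE]
    write_tsv(vm, "variants.tsv")
  }
  if (!is.null(kb$sequences)) {
    seqs <- kb$sequences[order(names(kb$sequences))]
    aa <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(aa, file.path(dir, "sequences.fasta"),
                                width = 60L)
  }
  invisible(dir)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>\n",
      "  proteoforms: ", length(x$proteoforms), "\n",
      "  reactions:   ", length(unique(x$participants$reaction_id)), "\n",
      "  pathways:    ", nrow(x$pathways), "\n",
      "  genes:       ", length(unique(x$gene_map$gene_name)), "\n",
      "  variants:    ", if (is.null(x$variant_map)) 0L else
        length(unique(x$variant_map$variant_id)), "\n",
      "  sequences:   ", if (is.null(x$sequences)) 0L else
        length(x$sequences), "\n", sep = "")
  invisible(x)
}

# --- internal KB accessors -------------------------------------------------

kb_parsed_proteoforms <- function(kb) {
  lapply(kb$proteoforms, parse_proteoform)
}

kb_accessions <- function(kb) {
  sort(unique(vapply(kb_parsed_proteoforms(kb), `[[`, character(1),
                     "accession")))
}

# unique reaction_id -> reaction_name table
kb_reactions <- function(kb) {
  r <- unique(kb$participants[, c("reaction_id", "reaction_name")])
  r[order(r$reaction_id), , drop = FALSE]
}

# parent chain from a pathway up to (and excluding) the root's NA parent
pathway_ancestors <- function(kb, pathway_id) {
  parent_of <- stats::setNames(kb$pathways$parent_id, kb$pathways$pathway_id)
  out <- character()
  cur <- parent_of[[pathway_id]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

pathway_top_level <- function(kb, pathway_id) {
  anc <- pathway_ancestors(kb, pathway_id)
  if (length(anc)) anc[length(anc)] else pathway_id
}

# direct + inherited reactions: a pathway's closure covers its own reactions
# and those of every descendant subpathway
pathway_reaction_closure <- function(kb, pathway_id) {
  children_of <- split(kb$pathways$pathway_id, kb$pathways$parent_id)
  own <- split(kb$pathway_reactions$reaction_id,
               kb$pathway_reactions$pathway_id)
  todo <- pathway_id
  seen <- character()
  rids <- character()
  while (length(todo)) {
    p <- todo[[1]]
    todo <- todo[-1]
    if (p %in% seen) next
    seen <- c(seen, p)
    rids <- c(rids, own[[p]])
    todo <- c(todo, children_of[[p]])
  }
  sort(unique(rids))
}

pathway_name <- function(kb, pathway_id) {
  kb$pathways$pathway_name[match(pathway_id, kb$pathways$pathway_id)]
}
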