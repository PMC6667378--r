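#' @title Mapping omics inputs to proteins and proteoforms
#'
#' @description Each supported input kind is modelled as a set of proteins or
#' proteoforms before matching: gene names resolve through the knowledge
#' base's gene map, variants (rsID or \code{chr:pos}) through the static
#' variant map, peptides through exact substring search in the protein
#' sequences, and modified peptides additionally translate peptide-relative
#' PTM positions into protein coordinates for every occurrence. Ambiguity
#' fans out: when a token maps to several accessions or sequence positions,
#' all possibilities enter the search. Unmapped tokens are kept in
#' \code{unresolved}.
#'
#' @name input_mapping
NULL

INPUT_KINDS <- c("gene", "variant", "protein", "peptide", "modified_peptide",
                 "proteoform")

new_input_entities <- function(kind, raw_count, entities, unresolved) {
  # entities: data.frame(token, entity) where entity is a canonical
  # proteoform serialization; rows unique on (token, entity)
  entities <- unique(entities)
  entities <- entities[order(entities$token, entities$entity), , drop = FALSE]
  rownames(entities) <- NULL
  structure(list(kind = kind, raw_count = raw_count, entities = entities,
                 unresolved = sort(unique(unresolved))),
            class = "input_entities")
}

#' @export
print.input_entities <- function(x, ...) {
  cat("<input_entities> kind=", x$kind, " raw=", x$raw_count,
      " resolved=", length(unique(x$entities$entity)),
      " unresolved=", length(x$unresolved), "\n", sep = "")
  invisible(x)
}

#' Distinct resolved entities of an input set
#'
#' @param x an \code{"input_entities"} object.
#' @return Character vector of canonical proteoform serializations.
#' @export
resolved_entities <- function(x) {
  stopifnot(inherits(x, "input_entities"))
  sort(unique(x$entities$entity))
}

entity_frame <- function(tokens, entities) {
  data.frame(token = tokens, entity = entities, stringsAsFactors = FALSE)
}

empty_entity_frame <- function() entity_frame(character(), character())

#' Map gene names to protein entities
#'
#' Case-sensitive exact lookup in the knowledge base's gene map; each gene
#' name yields one unmodified canonical proteoform per associated accession.
#'
#' @param genes character vector of gene names.
#' @param kb a \code{"knowledge_base"}.
#' @return An \code{"input_entities"} of kind \code{"gene"}.
#' @export
map_genes <- function(genes, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  gm <- kb$gene_map
  rows <- empty_entity_frame()
  unresolved <- character()
  for (g in genes) {
    acc <- unique(gm$accession[gm$gene_name == g])
    if (length(acc) == 0L) unresolved <- c(unresolved, g)
    else rows <- rbind(rows, entity_frame(g, paste0(acc, ";")))
  }
  new_input_entities("gene", length(genes), rows, unresolved)
}

#' Map variant identifiers to protein entities
#'
#' Resolves rsID and \code{chr:pos} tokens through the knowledge base's
#' static variant-to-accession table; a variant associated with several
#' accessions fans out to all of them.
#'
#' @param variants character vector of variant identifiers.
#' @param kb a \code{"knowledge_base"} with a variant map.
#' @return An \code{"input_entities"} of kind \code{"variant"}.
#' @export
map_variants <- function(variants, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  if (is.null(kb$variant_map)) {
    stop(condition_error("knowledge base has no variant map (variants.tsv)",
                         class = "proteopath_config_error"))
  }
  vm <- kb$variant_map
  rows <- empty_entity_frame()
  unresolved <- character()
  for (v in variants) {
    acc <- unique(vm$accession[vm$variant_id == v])
    if (length(acc) == 0L) unresolved <- c(unresolved, v)
    else rows <- rbind(rows, entity_frame(v, paste0(acc, ";")))
  }
  new_input_entities("variant", length(variants), rows, unresolved)
}

#' Treat protein accessions as entities
#'
#' Accessions absent from the knowledge base are recorded as unresolved.
#'
#' @param accessions character vector of accessions (an optional isoform
#'   suffix is preserved).
#' @param kb a \code{"knowledge_base"}.
#' @return An \code{"input_entities"} of kind \code{"protein"}.
#' @export
map_proteins <- function(accessions, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  known <- kb_accessions(kb)
  rows <- empty_entity_frame()
  unresolved <- character()
  for (a in accessions) {
    p <- parse_proteoform(a)
    if (p$accession %in% known) {
      # protein-level entities are modelled with an empty PTM set
      rows <- rbind(rows,
                    entity_frame(a, format_proteoform(proteoform(p$accession,
                                                                 p$isoform))))
    } else {
      unresolved <- c(unresolved, a)
    }
  }
  new_input_entities("protein", length(accessions), rows, unresolved)
}

#' Map peptide sequences to protein entities
#'
#' A peptide yields every accession whose sequence contains it as an exact
#' substring (no I/L equivalence, no missed-cleavage expansion).
#'
#' @param peptides character vector of amino-acid sequences.
#' @param kb a \code{"knowledge_base"} with sequences loaded.
#' @return An \code{"input_entities"} of kind \code{"peptide"}.
#' @export
map_peptides <- function(peptides, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  seqs <- require_sequences(kb)
  rows <- empty_entity_frame()
  unresolved <- character()
  for (pep in peptides) {
    hits <- names(seqs)[grepl(pep, seqs, fixed = TRUE)]
    if (length(hits) == 0L) unresolved <- c(unresolved, pep)
    else rows <- rbind(rows, entity_frame(pep, paste0(unique(hits), ";")))
  }
  new_input_entities("peptide", length(peptides), rows, unresolved)
}

#' Map modified peptides to candidate proteoforms
#'
#' For every exact occurrence of the peptide sequence at 1-based start
#' \code{s} in a protein sequence, each peptide-relative PTM position
#' \code{q} becomes protein site \code{s + q - 1}, yielding one candidate
#' proteoform per occurrence. Candidates are subsequently compared to the
#' reference proteoforms by the matching engine.
#'
#' @param lines character vector of \code{"SEQUENCE;type:pos,type:pos"}
#'   tokens (positions are peptide-relative and 1-based).
#' @param kb a \code{"knowledge_base"} with sequences loaded.
#' @return An \code{"input_entities"} of kind \code{"modified_peptide"}.
#' @export
map_modified_peptides <- function(lines, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  seqs <- require_sequences(kb)
  rows <- empty_entity_frame()
  unresolved <- character()
  for (line in lines) {
    parsed <- parse_modified_peptide(line)
    bad <- parsed$sites > nchar(parsed$sequence)
    if (any(bad)) {
      stop(condition_error("PTM position beyond peptide length in: ", line,
                           class = "proteopath_coordinate_error"))
    }
    found <- FALSE
    for (acc in names(seqs)) {
      starts <- peptide_occurrences(parsed$sequence, seqs[[acc]])
      for (s in starts) {
        cand <- proteoform(acc, NA, parsed$types, parsed$sites + s - 1L)
        rows <- rbind(rows, entity_frame(line, format_proteoform(cand)))
        found <- TRUE
      }
    }
    if (!found) unresolved <- c(unresolved, line)
  }
  new_input_entities("modified_peptide", length(lines), rows, unresolved)
}

parse_modified_peptide <- function(line) {
  semi <- regexpr(";", line, fixed = TRUE)
  if (semi == -1L) {
    stop(condition_error("modified peptide must be 'SEQUENCE;type:pos,...': ",
                         line, class = "proteopath_parse_error"))
  }
  sequence <- trimws(substr(line, 1L, semi - 1L))
  if (!nzchar(sequence)) {
    stop(condition_error("empty peptide sequence in: ", line,
                         class = "proteopath_parse_error"))
  }
  # reuse the proteoform PTM grammar on a placeholder accession
  ptms <- parse_proteoform(paste0("X;", substr(line, semi + 1L,
                                               nchar(line))))$ptms
  sites <- vapply(ptms, `[[`, integer(1), "site")
  if (anyNA(sites)) {
    stop(condition_error("modified-peptide PTM positions must be known: ",
                         line, class = "proteopath_coordinate_error"))
  }
  list(sequence = sequence,
       types = vapply(ptms, `[[`, character(1), "type"),
       sites = sites)
}

# all 1-based start positions of an exact (possibly overlapping) occurrence
peptide_occurrences <- function(peptide, sequence) {
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(peptide, substr(sequence, from, nchar(sequence)),
                   fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

#' Map already-formed proteoform strings
#'
#' Proteoforms whose accession is absent from the knowledge base are
#' unresolved.
#'
#' @param strings character vector in proteoform notation.
#' @param kb a \code{"knowledge_base"}.
#' @return An \code{"input_entities"} of kind \code{"proteoform"}.
#' @export
map_proteoforms <- function(strings, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  known <- kb_accessions(kb)
  rows <- empty_entity_frame()
  unresolved <- character()
  for (s in strings) {
    p <- parse_proteoform(s)
    if (p$accession %in% known) {
      rows <- rbind(rows, entity_frame(s, format_proteoform(p)))
    } else {
      unresolved <- c(unresolved, s)
    }
  }
  new_input_entities("proteoform", length(strings), rows, unresolved)
}

require_sequences <- function(kb) {
  if (is.null(kb$sequences)) {
    stop(condition_error("knowledge base has no protein sequences ",
                         "(sequences.fasta)",
                         class = "proteopath_config_error"))
  }
  kb$sequences
}

#' Read an input file of one of the supported kinds
#'
#' One token per line; blank lines and \code{"#"} comment lines are skipped.
#'
#' @param path file path.
#' @param kind one of \code{"gene"}, \code{"variant"}, \code{"protein"},
#'   \code{"peptide"}, \code{"modified_peptide"}, \code{"proteoform"}.
#' @return Character vector of raw tokens.
#' @export
read_input <- function(path, kind) {
  if (!kind %in% INPUT_KINDS) {
    stop(condition_error("unknown input kind: ", kind,
                         class = "proteopath_config_error"))
  }
  read_token_lines(path)
}

#' Resolve raw tokens of a given kind against the knowledge base
#'
#' Dispatch wrapper over the kind-specific \code{map_*} functions.
#'
#' @param tokens character vector of raw tokens.
#' @param kind input kind (see \code{\link{read_input}}).
#' @param kb a \code{"knowledge_base"}.
#' @return An \code{"input_entities"} object.
#' @export
map_input <- function(tokens, kind, kb) {
  switch(kind,
         gene = map_genes(tokens, kb),
         variant = map_variants(tokens, kb),
         protein = map_proteins(tokens, kb),
         peptide = map_peptides(tokens, kb),
         modified_peptide = map_modified_peptides(tokens, kb),
         proteoform = map_proteoforms(tokens, kb),
         stop(condition_error("unknown input kind: ", kind,
                              class = "proteopath_config_error")))
}
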