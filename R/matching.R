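#' @title Proteoform matching stringencies
#'
#' @description Eight matching types decide whether an input proteoform
#' corresponds to a reference proteoform. All of them first require identical
#' accession and isoform; they differ in how the two PTM multisets are
#' compared:
#' \describe{
#'   \item{STRICT}{equal PTM counts and a one-to-one pairing with exactly
#'     identical sites (no margin) and identical types; unknown sites pair
#'     only with unknown sites.}
#'   \item{SUPERSET}{every reference PTM matches some input PTM.}
#'   \item{SUBSET}{every input PTM matches some reference PTM.}
#'   \item{ONE}{at least one input PTM matches some reference PTM (false
#'     when the input carries no PTMs).}
#'   \item{ACCESSION}{accession + isoform identity only; PTMs ignored.}
#' }
#' \code{*_NO_TYPES} variants of SUPERSET/SUBSET/ONE ignore the modification
#' type. Site comparison tolerates a margin of \code{k} residues
#' (inclusive, \code{|input - ref| <= k}); the input type \code{"00000"} is a
#' wildcard matching any reference type.
#'
#' @name matching
NULL

MATCHING_TYPES <- c("STRICT", "SUPERSET", "SUPERSET_NO_TYPES", "SUBSET",
                    "SUBSET_NO_TYPES", "ONE", "ONE_NO_TYPES", "ACCESSION")

#' Matching configuration
#'
#' @param matching_type one of \code{"STRICT"}, \code{"SUPERSET"},
#'   \code{"SUPERSET_NO_TYPES"}, \code{"SUBSET"}, \code{"SUBSET_NO_TYPES"},
#'   \code{"ONE"}, \code{"ONE_NO_TYPES"}, \code{"ACCESSION"}
#'   (case-insensitive).
#' @param margin non-negative integer residue distance allowed between an
#'   input and a reference modification site. Ignored by STRICT (exact sites
#'   only) and by ACCESSION.
#' @return A \code{"matching_config"} object.
#' @export
matching_config <- function(matching_type = "SUBSET", margin = 0L) {
  matching_type <- toupper(matching_type)
  if (!matching_type %in% MATCHING_TYPES) {
    stop(condition_error("unknown matching type: ", matching_type,
                         " (expected one of ",
                         paste(MATCHING_TYPES, collapse = ", "), ")",
                         class = "proteopath_config_error"))
  }
  if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) ||
      margin < 0 || margin != as.integer(margin)) {
    stop(condition_error("margin must be a non-negative integer",
                         class = "proteopath_config_error"))
  }
  structure(list(matching_type = matching_type, margin = as.integer(margin)),
            class = "matching_config")
}

#' Compare two modification site coordinates
#'
#' Total predicate implementing the site-coordinate truth table: two known
#' positive coordinates match when \code{|input - ref| <= margin}
#' (inclusive); an unknown input site (\code{NA}) matches anything ("input is
#' less specific"); a known positive input matches an unknown reference site
#' (\code{NA} or the legacy sentinel \code{-1}; "input is more specific").
#' A raw input value of zero or below is never a valid sequence coordinate
#' and yields \code{FALSE}.
#'
#' @param input_site,ref_site integer coordinates or \code{NA} for unknown.
#' @param margin non-negative integer.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' match_coordinate(8, 13, 5)   # TRUE, in margin
#' match_coordinate(7, 13, 5)   # FALSE, out of margin
#' match_coordinate(0, 2, 5)    # FALSE, 0 is not a valid coordinate
#' @export
match_coordinate <- function(input_site, ref_site, margin = 0L) {
  if (!is.na(input_site) && input_site <= 0) return(FALSE)
  if (is.na(input_site)) return(TRUE)
  if (is.na(ref_site) || ref_site == -1) return(TRUE)
  if (ref_site <= 0) return(FALSE)
  abs(input_site - ref_site) <= margin
}

#' Compare two PTMs
#'
#' Site comparison follows \code{\link{match_coordinate}}; when
#' \code{use_types} is \code{TRUE} the type identifiers must be identical,
#' except that the input type \code{"00000"} is a wildcard matching any
#' reference type.
#'
#' @param input_ptm,ref_ptm PTMs as \code{list(type, site)} with \code{site}
#'   an integer or \code{NA} for unknown (as stored in a
#'   \code{"proteoform"}'s \code{ptms}).
#' @param margin non-negative integer residue tolerance.
#' @param use_types compare modification types as well as sites.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
match_ptm <- function(input_ptm, ref_ptm, margin = 0L, use_types = TRUE) {
  if (use_types && input_ptm$type != PTM_TYPE_WILDCARD &&
      input_ptm$type != ref_ptm$type) {
    return(FALSE)
  }
  match_coordinate(input_ptm$site, ref_ptm$site, margin)
}

# STRICT pairing: equal counts and a bijection with exact sites; types must
# be identical, with the input-side 00000 wildcard absorbing any type.
# Grouping by exact site key makes the assignment a per-site multiset check.
strict_ptms_match <- function(input_ptms, ref_ptms) {
  if (length(input_ptms) != length(ref_ptms)) return(FALSE)
  if (length(input_ptms) == 0L) return(TRUE)
  site_key <- function(m) if (is.na(m$site)) "?" else as.character(m$site)
  in_keys <- vapply(input_ptms, site_key, character(1))
  ref_keys <- vapply(ref_ptms, site_key, character(1))
  if (!identical(sort(in_keys), sort(ref_keys))) return(FALSE)
  for (key in unique(in_keys)) {
    in_types <- sort(vapply(input_ptms[in_keys == key], `[[`, character(1),
                            "type"))
    ref_types <- sort(vapply(ref_ptms[ref_keys == key], `[[`, character(1),
                             "type"))
    literal <- in_types[in_types != PTM_TYPE_WILDCARD]
    # each literal input type must consume one identical reference type;
    # wildcards absorb whatever is left
    for (ty in literal) {
      hit <- match(ty, ref_types)
      if (is.na(hit)) return(FALSE)
      ref_types <- ref_types[-hit]
    }
  }
  TRUE
}

#' Compare two proteoforms under a matching configuration
#'
#' @param input_p,ref_p \code{"proteoform"} objects (input versus reference).
#' @param config a \code{\link{matching_config}}.
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' a <- parse_proteoform("P01308;00798:31")
#' b <- parse_proteoform("P01308;00087:53,00798:31,00798:43")
#' match_proteoform(a, b, matching_config("SUBSET"))    # TRUE
#' match_proteoform(a, b, matching_config("SUPERSET"))  # FALSE
#' @export
match_proteoform <- function(input_p, ref_p, config) {
  stopifnot(inherits(input_p, "proteoform"), inherits(ref_p, "proteoform"),
            inherits(config, "matching_config"))
  if (input_p$accession != ref_p$accession) return(FALSE)
  if (!identical(is.na(input_p$isoform), is.na(ref_p$isoform))) return(FALSE)
  if (!is.na(input_p$isoform) && input_p$isoform != ref_p$isoform) {
    return(FALSE)
  }
  type <- config$matching_type
  if (type == "ACCESSION") return(TRUE)
  if (type == "STRICT") return(strict_ptms_match(input_p$ptms, ref_p$ptms))
  use_types <- !endsWith(type, "_NO_TYPES")
  margin <- config$margin
  one_matches <- function(m, pool) {
    any(vapply(pool, function(r) match_ptm(m, r, margin, use_types),
               logical(1)))
  }
  base <- sub("_NO_TYPES$", "", type)
  switch(base,
    SUBSET = all(vapply(input_p$ptms, one_matches, logical(1),
                        pool = ref_p$ptms)),
    SUPERSET = all(vapply(ref_p$ptms, function(r) {
      any(vapply(input_p$ptms, function(m) match_ptm(m, r, margin, use_types),
                 logical(1)))
    }, logical(1))),
    ONE = length(input_p$ptms) > 0L &&
      any(vapply(input_p$ptms, one_matches, logical(1), pool = ref_p$ptms))
  )
}

#' Match a collection of proteoforms against a reference set
#'
#' Evaluates \code{\link{match_proteoform}} for every (input, reference) pair
#' and returns the matching pairs in deterministic order: input order, then
#' reference canonical-serialization order.
#'
#' @param inputs list of input \code{"proteoform"} objects.
#' @param references list of reference \code{"proteoform"} objects, or a
#'   character vector of proteoform strings.
#' @param config a \code{\link{matching_config}}.
#' @return A data.frame with columns \code{input}, \code{reference} (both
#'   canonical serializations), \code{matching_type}, \code{margin}.
#' @export
match_against_kb <- function(inputs, references, config) {
  if (is.character(references)) references <- lapply(references,
                                                     parse_proteoform)
  ref_str <- vapply(references, format_proteoform, character(1))
  ord <- order(ref_str)
  references <- references[ord]
  ref_str <- ref_str[ord]
  # references indexed by accession: only same-accession pairs can match
  ref_acc <- vapply(references, `[[`, character(1), "accession")
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    p <- inputs[[i]]
    cand <- which(ref_acc == p$accession)
    hit <- cand[vapply(cand, function(j) {
      match_proteoform(p, references[[j]], config)
    }, logical(1))]
    if (length(hit)) {
      rows[[i]] <- data.frame(input = format_proteoform(p),
                              reference = ref_str[hit],
                              matching_type = config$matching_type,
                              margin = config$margin,
                              stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(input = character(), reference = character(),
                      matching_type = character(), margin = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
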