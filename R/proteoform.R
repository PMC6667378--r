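#' @title Proteoforms and posttranslational modifications
#'
#' @description A proteoform is one form of a protein product: a UniProt
#' accession, an optional isoform number (absent means the canonical isoform)
#' and a multiset of posttranslational modifications (PTMs). Each PTM carries
#' a 5-digit PSI-MOD type identifier (e.g. \code{"00046"} =
#' O-phospho-L-serine) and a 1-based residue coordinate on the UniProt
#' sequence, or \code{NA} when the site is unknown. The reserved type
#' \code{"00000"} is a query wildcard matching any modification type.
#'
#' The text notation is \code{ACCESSION[-ISOFORM];TYPE:SITE,TYPE:SITE,...}
#' where \code{TYPE} may carry an optional \code{MOD:} prefix and \code{SITE}
#' is a positive integer or \code{?} (unknown). The first \code{";"}
#' terminates the accession; the PTM tokens may be separated by \code{","} or
#' \code{";"} on input, and are always serialized with \code{","}.
#'
#' @name proteoform
NULL

PTM_TYPE_WILDCARD <- "00000"

new_ptm <- function(type_id, site) {
  if (!grepl("^[0-9]{5}$", type_id)) {
    stop(condition_error("invalid PTM type identifier (need 5 decimal digits): ",
                         type_id, class = "proteopath_type_error"))
  }
  if (!is.na(site)) {
    if (!is.numeric(site) || site != as.integer(site) || site < 1) {
      stop(condition_error("invalid PTM site coordinate (need integer >= 1): ",
                           site, class = "proteopath_coordinate_error"))
    }
    site <- as.integer(site)
  } else {
    site <- NA_integer_
  }
  list(type = type_id, site = site)
}

#' Construct a proteoform
#'
#' @param accession non-empty UniProt accession (treated as an opaque token).
#' @param isoform optional positive integer isoform number; \code{NA} or
#'   \code{NULL} means the canonical isoform.
#' @param ptm_types,ptm_sites parallel vectors typing and locating the PTM
#'   multiset; \code{ptm_sites} entries may be \code{NA} for unknown sites.
#'   Duplicate (type, site) pairs are preserved.
#' @return An object of class \code{"proteoform"}.
#' @examples
#' proteoform("P04637", ptm_types = "00046", ptm_sites = 15)
#' @export
proteoform <- function(accession, isoform = NA, ptm_types = character(),
                       ptm_sites = integer()) {
  if (!is.character(accession) || length(accession) != 1L ||
      !nzchar(trimws(accession))) {
    stop(condition_error("accession must be a non-empty string",
                         class = "proteopath_parse_error"))
  }
  if (is.null(isoform)) isoform <- NA
  if (!is.na(isoform)) {
    if (!is.numeric(isoform) || isoform != as.integer(isoform) || isoform < 1) {
      stop(condition_error("isoform must be a positive integer or NA",
                           class = "proteopath_parse_error"))
    }
    isoform <- as.integer(isoform)
  } else {
    isoform <- NA_integer_
  }
  stopifnot(length(ptm_types) == length(ptm_sites))
  ptms <- mapply(new_ptm, as.character(ptm_types), ptm_sites,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(list(accession = accession, isoform = isoform,
                 ptms = sort_ptms(ptms)),
            class = "proteoform")
}

# canonical PTM order: (type_id, site) with unknown sites last
sort_ptms <- function(ptms) {
  if (length(ptms) == 0L) return(list())
  types <- vapply(ptms, `[[`, character(1), "type")
  sites <- vapply(ptms, `[[`, integer(1), "site")
  ptms[order(types, is.na(sites), sites)]
}

ptm_count <- function(p) length(p$ptms)

#' Parse the proteoform text notation
#'
#' @param text a single proteoform string, e.g.
#'   \code{"P01308;MOD:00087:53,MOD:00798:31,MOD:00798:43"} or
#'   \code{"P31749-3;00046:473"}. Site \code{"?"} or \code{"null"} denotes an
#'   unknown position.
#' @return A \code{"proteoform"} object.
#' @examples
#' parse_proteoform("P31749-3;00046:473")
#' @export
parse_proteoform <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop(condition_error("empty proteoform string",
                         class = "proteopath_parse_error"))
  }
  semi <- regexpr(";", text, fixed = TRUE)
  if (semi == -1L) {
    acc_part <- text
    ptm_part <- ""
  } else {
    acc_part <- substr(text, 1L, semi - 1L)
    ptm_part <- substr(text, semi + 1L, nchar(text))
  }
  if (!nzchar(acc_part)) {
    stop(condition_error("missing accession in proteoform string: ", text,
                         class = "proteopath_parse_error"))
  }
  isoform <- NA_integer_
  accession <- acc_part
  m <- regmatches(acc_part, regexec("^(.*)-([0-9]+)$", acc_part))[[1]]
  if (length(m) == 3L) {
    accession <- m[2]
    isoform <- as.integer(m[3])
  }
  types <- character()
  sites <- integer()
  if (nzchar(trimws(ptm_part))) {
    # Fig-style dialect separates PTMs with ";", Methods-style with ","
    tokens <- strsplit(ptm_part, "[,;]")[[1]]
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      raw <- sub("^MOD:", "", tok)
      colon <- regexpr(":", raw, fixed = TRUE)
      if (colon == -1L) {
        stop(condition_error("malformed PTM token (missing ':'): ", tok,
                             class = "proteopath_parse_error"))
      }
      type_id <- substr(raw, 1L, colon - 1L)
      site_tok <- substr(raw, colon + 1L, nchar(raw))
      if (!grepl("^[0-9]{5}$", type_id)) {
        stop(condition_error("invalid PTM type identifier in token '", tok,
                             "' (need 5 decimal digits)",
                             class = "proteopath_type_error"))
      }
      if (site_tok %in% c("?", "null")) {
        site <- NA_integer_
      } else if (grepl("^-?[0-9]+$", site_tok)) {
        site <- as.integer(site_tok)
        if (site < 1L) {
          stop(condition_error("invalid PTM site in token '", tok,
                               "': zero and negative values are invalid ",
                               "sequence coordinates",
                               class = "proteopath_coordinate_error"))
        }
      } else {
        stop(condition_error("invalid PTM site in token '", tok,
                             "': must be a positive integer, '?' or 'null'",
                             class = "proteopath_coordinate_error"))
      }
      types <- c(types, type_id)
      sites <- c(sites, site)
    }
  }
  proteoform(accession, isoform, types, if (length(sites)) sites else integer())
}

#' Serialize a proteoform to its canonical notation
#'
#' PTMs are emitted in canonical order (type identifier, then site with
#' unknown sites last) separated by commas; unknown sites serialize as
#' \code{"?"}. \code{parse_proteoform(format_proteoform(p))} equals \code{p}.
#'
#' @param p a \code{"proteoform"} object.
#' @return A single string.
#' @export
format_proteoform <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  acc <- if (is.na(p$isoform)) p$accession else
    paste0(p$accession, "-", p$isoform)
  ptms <- vapply(p$ptms, function(m) {
    paste0(m$type, ":", if (is.na(m$site)) "?" else m$site)
  }, character(1))
  paste0(acc, ";", paste(ptms, collapse = ","))
}

#' @export
format.proteoform <- function(x, ...) format_proteoform(x)

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", format_proteoform(x), "\n", sep = "")
  invisible(x)
}

#' Proteoform equality
#'
#' Two proteoforms are equal when accession, isoform and the PTM multiset
#' coincide; PTM order is irrelevant.
#'
#' @param a,b \code{"proteoform"} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
proteoform_equal <- function(a, b) {
  identical(format_proteoform(a), format_proteoform(b))
}

#' Convert a phosphosite to a single-PTM proteoform
#'
#' A phosphosite (accession, phosphorylated residue, position) becomes a
#' canonical-isoform proteoform with one phosphorylation PTM: type
#' \code{00046} for serine, \code{00047} for threonine, \code{00048} for
#' tyrosine.
#'
#' @param accession UniProt accession.
#' @param residue one of \code{"S"}, \code{"T"}, \code{"Y"}.
#' @param position positive 1-based residue index.
#' @return A \code{"proteoform"} object.
#' @examples
#' format_proteoform(phosphosite_to_proteoform("P04637", "S", 15))
#' @export
phosphosite_to_proteoform <- function(accession, residue, position) {
  types <- c(S = "00046", T = "00047", Y = "00048")
  if (!residue %in% names(types)) {
    stop(condition_error("phosphosite residue must be one of S, T, Y, got: ",
                         residue, class = "proteopath_parse_error"))
  }
  if (!is.numeric(position) || position != as.integer(position) ||
      position < 1) {
    stop(condition_error("phosphosite position must be a positive integer",
                         class = "proteopath_coordinate_error"))
  }
  proteoform(accession, NA, types[[residue]], as.integer(position))
}

#' Read a proteoform list file
#'
#' UTF-8 text, one proteoform-notation string per line; blank lines and lines
#' starting with \code{"#"} are ignored.
#'
#' @param path file path.
#' @return A list of \code{"proteoform"} objects.
#' @export
read_proteoform_list <- function(path) {
  lapply(read_token_lines(path), parse_proteoform)
}

# shared line reader: one token per line, '#' comments and blanks skipped
read_token_lines <- function(path) {
  if (!file.exists(path)) {
    stop(condition_error("input file not found: ", path,
                         class = "proteopath_config_error"))
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("input file contains no entries: ", path)
  }
  lines
}

condition_error <- function(..., class) {
  structure(class = c(class, "proteopath_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}
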