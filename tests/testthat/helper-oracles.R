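# Independent brute-force oracles, written as literal transcriptions of the
# quantifier definitions; deliberately naive (permutation search for the
# strict bijection) and shared by the unit and acceptance tests.

oracle_site_ok <- function(input, ref, margin) {
  if (!is.na(input) && input <= 0) return(FALSE)
  if (is.na(input)) return(TRUE)
  if (is.na(ref) || ref == -1) return(TRUE)
  if (ref <= 0) return(FALSE)
  abs(input - ref) <= margin
}

oracle_ptm_ok <- function(mi, mr, margin, use_types) {
  if (use_types && mi$type != "00000" && mi$type != mr$type) return(FALSE)
  oracle_site_ok(mi$site, mr$site, margin)
}

all_permutations <- function(n) {
  if (n == 0) return(list(integer()))
  if (n == 1) return(list(1L))
  out <- list()
  for (perm in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
    }
  }
  out
}

# strict pair predicate: exactly identical known sites or both unknown;
# identical types with the input-side wildcard
oracle_strict_pair <- function(mi, mr) {
  site <- if (is.na(mi$site) || is.na(mr$site)) {
    is.na(mi$site) && is.na(mr$site)
  } else {
    mi$site >= 1 && mi$site == mr$site
  }
  site && (mi$type == "00000" || mi$type == mr$type)
}

oracle_match_proteoform <- function(a, b, type, margin) {
  if (a$accession != b$accession) return(FALSE)
  if (!identical(is.na(a$isoform), is.na(b$isoform))) return(FALSE)
  if (!is.na(a$isoform) && a$isoform != b$isoform) return(FALSE)
  A <- a$ptms
  B <- b$ptms
  use_types <- !endsWith(type, "_NO_TYPES")
  base <- sub("_NO_TYPES$", "", type)
  if (base == "ACCESSION") return(TRUE)
  if (base == "STRICT") {
    if (length(A) != length(B)) return(FALSE)
    if (length(A) == 0) return(TRUE)
    for (perm in all_permutations(length(A))) {
      ok <- TRUE
      for (i in seq_along(A)) {
        if (!oracle_strict_pair(A[[i]], B[[perm[i]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(TRUE)
    }
    return(FALSE)
  }
  exists_ref_for <- function(mi) {
    any(vapply(B, function(mr) oracle_ptm_ok(mi, mr, margin, use_types),
               logical(1)))
  }
  exists_input_for <- function(mr) {
    any(vapply(A, function(mi) oracle_ptm_ok(mi, mr, margin, use_types),
               logical(1)))
  }
  switch(base,
         SUBSET = all(vapply(A, exists_ref_for, logical(1))),
         SUPERSET = all(vapply(B, exists_input_for, logical(1))),
         ONE = length(A) > 0 && any(vapply(A, exists_ref_for, logical(1))))
}

# textbook Benjamini-Hochberg, written directly from the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adjusted <- numeric(m)
  sorted <- p[ord]
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, sorted[i] * m / i)
    adjusted[i] <- running_min
  }
  out <- numeric(m)
  out[ord] <- pmin(adjusted, 1)
  out
}

# extended-precision right-tail binomial: direct mass summation
oracle_binom_right_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}
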