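#' Synthetic substructure-key dictionary (KRFP-sized stand-in)
#'
#' The Klekota-Roth fingerprint is a non-hashed substructure fingerprint of
#' 4860 SMARTS-defined keys, so each bit corresponds to one exact fragment.
#' The original key list is distributed with external fingerprinting software
#' and is not redistributed here; this function generates a *synthetic*
#' stand-in dictionary of the same size and format — 4860 distinct, valid
#' SMARTS patterns (linear chains over aliphatic C/N/O/S of length 1 to 6,
#' enumerated in a fixed order) — so that every code path taking a key
#' dictionary can be exercised end to end. Substitute the real key file via
#' the `keys` argument of [compute_krfp()] for production fingerprints.
#'
#' @param n Number of keys (default 4860, the KRFP bit count).
#' @return A tibble with columns `bit` (0-based integer index) and `smarts`.
#'   The dictionary generation scheme is recorded in the `"generator"`
#'   attribute.
#' @export
#' @examples
#' keys <- synthetic_krfp_keys()
#' nrow(keys)
synthetic_krfp_keys <- function(n = 4860) {
  stopifnot(n >= 1)
  symbols <- c("C", "N", "O", "S")
  out <- character(0)
  len <- 1L
  while (length(out) < n) {
    idx <- arrayInd(seq_len(length(symbols)^len),
                    rep(length(symbols), len))
    # enumerate chains of this length in lexicographic order
    chains <- apply(idx[, rev(seq_len(len)), drop = FALSE], 1L,
                    function(i) paste(symbols[i], collapse = ""))
    out <- c(out, sort(chains))
    len <- len + 1L
  }
  out <- out[seq_len(n)]
  res <- tibble::tibble(bit = seq_along(out) - 1L, smarts = out)
  attr(res, "generator") <- "synthetic-linear-chain-v1"
  res
}

#' Compute a substructure-key fingerprint matrix from molecular structures
#'
#' Entry (i, j) is 1 when SMARTS key j matches molecule i as a substructure,
#' 0 otherwise. Bit ids follow the key-dictionary order. Matching uses the
#' OpenBabel SMARTS engine (via ChemmineR/ChemmineOB), whose aromaticity
#' perception may differ bit-for-bit from other toolkits; the matcher is
#' recorded in the result's `"matcher"` attribute. Molecules that fail to
#' parse are dropped with a warning naming them, never silently skipped.
#'
#' @param structures Either a data frame with columns `compound_id` and
#'   `smiles`, or a `ChemmineR::SDFset`.
#' @param keys Key dictionary: data frame with columns `bit` (integer id) and
#'   `smarts`, e.g. [synthetic_krfp_keys()] or a parsed real KRFP key file.
#' @return A fingerprint tibble (first column `compound_id`, then one 0/1
#'   column per key, named by `keys$bit`).
#' @export
compute_krfp <- function(structures, keys) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("compute_krfp() requires the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  stopifnot(is.data.frame(keys), all(c("bit", "smarts") %in% names(keys)))
  if (nrow(keys) == 0) stop("empty key dictionary", call. = FALSE)
  if (anyDuplicated(keys$bit)) stop("duplicate bit ids in key dictionary", call. = FALSE)

  if (methods::is(structures, "SDFset")) {
    sdf <- structures
    ids <- ChemmineR::sdfid(sdf)
  } else {
    stopifnot(is.data.frame(structures),
              all(c("compound_id", "smiles") %in% names(structures)))
    ids <- as.character(structures$compound_id)
    ok <- vapply(seq_len(nrow(structures)), function(i) {
      !inherits(tryCatch(ChemmineR::smiles2sdf(structures$smiles[i]),
                         error = function(e) e), "error")
    }, logical(1))
    if (any(!ok)) {
      warning("dropped ", sum(!ok), " unparsable structure(s): ",
              paste(ids[!ok], collapse = ", "), call. = FALSE)
    }
    if (!any(ok)) {
      return(empty_fingerprints(keys$bit))
    }
    ids <- ids[ok]
    sdf <- ChemmineR::smiles2sdf(stats::setNames(structures$smiles[ok], ids))
  }
  if (length(sdf) == 0) {
    return(empty_fingerprints(keys$bit))
  }
  mat <- matrix(0L, nrow = length(sdf), ncol = nrow(keys))
  for (j in seq_len(nrow(keys))) {
    hits <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, keys$smarts[j], uniqueMatches = FALSE),
      error = function(e) stop("unparsable SMARTS for key bit ", keys$bit[j],
                               ": ", keys$smarts[j], call. = FALSE))
    mat[, j] <- as.integer(hits > 0)
  }
  out <- fingerprint_tibble(mat, ids, keys$bit)
  attr(out, "matcher") <- paste0("ChemmineOB/OpenBabel (ChemmineR ",
                                 as.character(utils::packageVersion("ChemmineR")), ")")
  out
}

empty_fingerprints <- function(bit_ids) {
  fingerprint_tibble(matrix(0L, nrow = 0, ncol = length(bit_ids)),
                     character(0), bit_ids)
}

#' Read SMILES structures from a text file
#'
#' One molecule per line: a SMILES string optionally followed by whitespace
#' and an identifier. Missing identifiers default to `mol<line>`.
#'
#' @param path Path to the SMILES file.
#' @return A tibble with columns `compound_id` and `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tibble::tibble(
    compound_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}
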