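# N-glycosylation sequon detection: N-X-(S|T) with X != P.

#' Find N-glycosylation sequons
#'
#' Scans protein chains for the N-X-(S|T) tripeptide motif (X not
#' proline) that marks a potential N-linked glycosylation site. An
#' asparagine followed by proline (e.g. the N-P-I in DTGNYTVILTNPISK) is
#' not a sequon and is excluded.
#'
#' @param chains A tibble with columns `chain_id` and `sequence`, or a
#'   (optionally named) character vector of sequences.
#' @return A tibble with one row per sequon: `chain_id`, `position`
#'   (1-based index of the Asn), `motif` (the three residues), `occupied`
#'   (logical, `NA` until occupancy has been assessed), ordered by chain
#'   then ascending position.
#' @examples
#' find_sequons(c(trap = "DTGNYTVILTNPISK"))
#' @export
find_sequons <- function(chains) {
  chains <- as_chain_tbl(chains)
  purrr::pmap_dfr(chains[c("chain_id", "sequence")], function(chain_id, sequence) {
    res <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(res)
    if (n < 3) {
      return(tibble::tibble(chain_id = character(), position = integer(),
                            motif = character(), occupied = logical()))
    }
    i <- seq_len(n - 2)
    hit <- res[i] == "N" & res[i + 1] != "P" & res[i + 2] %in% c("S", "T")
    pos <- i[hit]
    tibble::tibble(
      chain_id = chain_id,
      position = pos,
      motif = vapply(pos, function(p) paste(res[p:(p + 2)], collapse = ""), character(1)),
      occupied = NA
    )
  })
}

# normalise chain input to tibble(chain_id, sequence)
as_chain_tbl <- function(chains) {
  if (is.character(chains)) {
    ids <- names(chains)
    if (is.null(ids)) ids <- paste0("chain", seq_along(chains))
    chains <- tibble::tibble(chain_id = ids, sequence = unname(chains))
  }
  stopifnot(is.data.frame(chains), all(c("chain_id", "sequence") %in% names(chains)))
  if (any(!nzchar(chains$sequence))) stop("empty chain sequence", call. = FALSE)
  bad <- stringr::str_remove_all(chains$sequence, "[ACDEFGHIKLMNPQRSTVWY]")
  if (any(nzchar(bad))) {
    stop("non-canonical residue code(s): ",
         paste(unique(unlist(strsplit(bad[nzchar(bad)], ""))), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(chains)
}
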