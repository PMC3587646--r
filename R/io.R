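# Readers and writers for the pipeline's exchange formats: FASTA chains,
# CSV peak lists, TSV disulfide topologies and glycan libraries, MGF for
# optional MS/MS confirmation, and a YAML run configuration.

#' Read protein chains from FASTA
#'
#' @param path FASTA file.
#' @return Chain tibble (`chain_id`, `sequence`).
#' @export
read_fasta_chains <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    chains <- tibble::tibble(chain_id = names(aa),
                             sequence = unname(as.character(aa)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    chains <- tibble::tibble(
      chain_id = sub("^>\\s*", "", lines[hdr]),
      sequence = vapply(split(lines[!hdr], id[!hdr]), paste, character(1), collapse = "")
    )
  }
  chains$chain_id <- sub("\\s.*$", "", chains$chain_id)
  as_chain_tbl(chains)
}

#' Write protein chains to FASTA
#'
#' @param chains Chain tibble.
#' @param path Output file.
#' @export
write_fasta_chains <- function(chains, path) {
  chains <- as_chain_tbl(chains)
  writeLines(paste0(">", chains$chain_id, "\n", chains$sequence), path)
  invisible(path)
}

#' Read an observed peak list from CSV
#'
#' Expected columns: `observed_mass_or_mz` (required; MH+ when `charge`
#' is empty, m/z otherwise), `charge`, `retention_time`, `intensity`
#' (optional).
#'
#' @param path CSV file.
#' @return Peak tibble with column `observed` plus any optional columns.
#' @export
read_peak_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"observed_mass_or_mz" %in% names(df)) {
    stop("peak CSV must have column 'observed_mass_or_mz'", call. = FALSE)
  }
  df <- dplyr::rename(df, observed = "observed_mass_or_mz")
  if (any(df$observed <= 0)) stop("observed masses must be > 0", call. = FALSE)
  if ("charge" %in% names(df) && any(!is.na(df$charge) & df$charge < 1)) {
    stop("charge must be >= 1", call. = FALSE)
  }
  df
}

#' Read a disulfide topology from TSV
#'
#' Columns `chain_a`, `pos_a`, `chain_b`, `pos_b`.
#'
#' @param path TSV file.
#' @return Bond tibble.
#' @export
read_topology_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("chain_a", "pos_a", "chain_b", "pos_b") %in% names(df)))
  df
}

#' Read precursor spectra from an MGF file
#'
#' Minimal Mascot-generic-format reader for MS/MS confirmation: one row
#' per `BEGIN IONS` block with the precursor m/z, charge, optional title,
#' and fragment peaks as a list-column.
#'
#' @param path MGF file.
#' @return Tibble: `title`, `pepmass`, `charge`, `fragments` (list of
#'   two-column `mz`/`intensity` tibbles).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(begins) == length(ends))
  purrr::map2_dfr(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    peaks <- do.call(rbind, strsplit(block[!kv & nzchar(block)], "[ \t]+"))
    frag <- if (is.null(peaks)) {
      tibble::tibble(mz = numeric(), intensity = numeric())
    } else {
      tibble::tibble(mz = as.numeric(peaks[, 1]),
                     intensity = if (ncol(peaks) > 1) as.numeric(peaks[, 2]) else NA_real_)
    }
    pm <- vals[match("PEPMASS", keys)]
    ch <- vals[match("CHARGE", keys)]
    tibble::tibble(
      title = vals[match("TITLE", keys)],
      pepmass = as.numeric(strsplit(pm, "[ \t]+")[[1]][1]),
      charge = if (is.na(ch)) NA_integer_ else as.integer(sub("\\+$", "", ch)),
      fragments = list(frag)
    )
  })
}

#' Confirm a peptide assignment against an MS/MS spectrum
#'
#' Counts how many predicted singly charged b/y ions of a peptide are
#' present in a fragment spectrum within tolerance.
#'
#' @param spectrum A `fragments` tibble (`mz`, `intensity`).
#' @param sequence Peptide sequence.
#' @param mod_deltas Optional per-residue modification deltas.
#' @param tol_da Fragment tolerance in Da.
#' @return One-row tibble: `n_predicted`, `n_matched`, `fraction`.
#' @export
confirm_fragments <- function(spectrum, sequence, mod_deltas = NULL, tol_da = 0.5) {
  pred <- fragment_ions(sequence, mod_deltas)
  hit <- vapply(pred$mz, function(m) any(abs(spectrum$mz - m) <= tol_da), logical(1))
  tibble::tibble(n_predicted = nrow(pred), n_matched = sum(hit),
                 fraction = sum(hit) / nrow(pred))
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A named list of run parameters.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    fasta = NULL, peaks_peptide_map = NULL, peaks_nonreduced = NULL,
    peaks_glyco = NULL, topology = NULL, glycan_library = NULL,
    tol_da = 0.5, tol_ppm = NULL, protease = "trypsin", max_missed = 0,
    nonreduced_missed = 1, pngasef = TRUE, check_isotope = TRUE,
    pka = as.list(pka_bjellqvist()), seed = 1, strict = FALSE,
    out_dir = "."
  )
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}
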