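# Readers and writers for the pipeline's plain-text interchange formats:
# per-species FASTA alignments, tab-separated metadata / abundance / COG /
# pairing tables, and the truth JSON. All writers are stable-sorted so
# reruns diff cleanly.

#' Write a generated cohort to a directory
#'
#' Emits `metadata.tsv`, one FASTA alignment per species (under
#' `alignments/`), `abundance.tsv`, `cog.tsv`, `pairings.tsv` (the
#' reference donor-recipient pairings) and `truth.json`. Species with no
#' detected strains are omitted and logged. The emitted files round-trip
#' losslessly through [read_cohort()].
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmt_cohort"))
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable directory: ", dir)
  files <- character(0)

  f <- file.path(dir, "metadata.tsv")
  readr::write_tsv(cohort$roster, f)
  files <- c(files, f)

  for (sp in sort(names(cohort$alignments))) {
    recs <- cohort$alignments[[sp]]
    if (length(recs) == 0) {
      eg_log("emit", paste0("species '", sp, "' has no detected strains; ",
                            "alignment file omitted"))
      next
    }
    recs <- recs[order(names(recs))]
    f <- file.path(dir, "alignments", paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), f)
    files <- c(files, f)
  }

  f <- file.path(dir, "abundance.tsv")
  readr::write_tsv(cohort$abundance, f)
  files <- c(files, f)

  f <- file.path(dir, "cog.tsv")
  readr::write_tsv(cohort$cog, f, na = "NA")
  files <- c(files, f)

  f <- file.path(dir, "pairings.tsv")
  readr::write_tsv(true_pairings_table(cohort$truth), f)
  files <- c(files, f)

  f <- file.path(dir, "truth.json")
  truth <- cohort$truth
  jsonlite::write_json(
    list(true_pairings = truth$true_pairings,
         engraftment_events = truth$engraftment_events,
         lineage_assignment = truth$lineage_assignment),
    f, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Read a cohort directory back into memory
#'
#' @param dir Directory written by [emit_cohort()] (or files in the same
#'   layout).
#' @return List with `roster`, `alignments`, `abundance`, `cog`, `truth`
#'   (`NULL` when `truth.json` is absent), `reference`.
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  pair_path <- file.path(dir, "pairings.tsv")
  list(roster = read_metadata(file.path(dir, "metadata.tsv")),
       alignments = read_alignment_dir(file.path(dir, "alignments")),
       abundance = read_abundance(file.path(dir, "abundance.tsv")),
       cog = read_cog(file.path(dir, "cog.tsv")),
       truth = if (file.exists(truth_path)) read_truth(truth_path) else NULL,
       reference = if (file.exists(pair_path))
         read_pairings(pair_path) else NULL)
}

#' Read per-species FASTA alignments from a directory
#'
#' Each `*.fasta`/`*.fa` file holds one species' alignment; the record
#' header is the sample id. Wrapped lines and lowercase residues are
#' tolerated (residues are uppercased on read).
#'
#' @param dir Directory of FASTA files.
#' @return Named list (species -> named character vector of sequences).
#' @export
read_alignment_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.(fasta|fa)$",
                           full.names = TRUE))
  out <- lapply(paths, read_alignment_fasta)
  names(out) <- sub("\\.(fasta|fa)$", "", basename(paths))
  out
}

#' @rdname read_alignment_dir
#' @param path A single FASTA file.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (length(unique(nchar(seqs))) > 1) {
    stop("alignment length mismatch in ", path)
  }
  seqs
}

read_tsv_checked <- function(path, required, col_types) {
  tb <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                         na = "NA", progress = FALSE))
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    stop(path, ": malformed row(s) at line(s) ",
         paste(utils::head(prob$row, 5), collapse = ", "))
  }
  tb
}

#' Read the sample metadata table
#' @param path TSV with columns `sample_id`, `subject_id`, `role`,
#'   `timepoint`, `read_count`.
#' @return Tibble (duplicate sample ids are an error).
#' @export
read_metadata <- function(path) {
  tb <- read_tsv_checked(path, c("sample_id", "subject_id", "role",
                                 "timepoint", "read_count"),
                         readr::cols(sample_id = "c", subject_id = "c",
                                     role = "c", timepoint = "c",
                                     read_count = "i"))
  roster_check(tb)
}

#' Read the wide species relative-abundance table
#' @param path TSV: `sample_id` column plus one numeric column per species
#'   (and optionally `UNKNOWN`).
#' @return Tibble.
#' @export
read_abundance <- function(path) {
  tb <- read_tsv_checked(path, "sample_id",
                         readr::cols(sample_id = "c",
                                     .default = readr::col_double()))
  if (anyDuplicated(tb$sample_id)) stop(path, ": duplicate sample_id")
  tb
}

#' Read the long gene-to-COG-category annotation table
#' @param path TSV with columns `sample_id`, `gene_id`, `category`
#'   (`NA` = unannotated; multi-category genes occupy multiple rows).
#' @return Tibble.
#' @export
read_cog <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene_id", "category"),
                   readr::cols(sample_id = "c", gene_id = "c",
                               category = "c"))
}

#' Read a long donor-recipient pairing table
#' @param path TSV with columns `recipient`, `donor`.
#' @return Tibble.
#' @export
read_pairings <- function(path) {
  read_tsv_checked(path, c("recipient", "donor"),
                   readr::cols(recipient = "c", donor = "c"))
}

#' Read a truth JSON written by [emit_cohort()]
#' @param path JSON file.
#' @return List with `true_pairings`, `engraftment_events`,
#'   `lineage_assignment`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(true_pairings = lapply(x$true_pairings, as.character),
       engraftment_events = tibble::as_tibble(x$engraftment_events),
       lineage_assignment = tibble::as_tibble(x$lineage_assignment))
}

#' Write a distance table as TSV
#'
#' Long format (`species`, `sample_a`, `sample_b`, `p_mismatch`,
#' `raw_jc69`, `normalised`), stably sorted, with `Inf` spelling the
#' saturation sentinel.
#'
#' @param table Distance table.
#' @param path Output path.
#' @export
write_distances <- function(table, path) {
  readr::write_tsv(dplyr::arrange(table, .data$species, .data$sample_a,
                                  .data$sample_b), path)
}

#' Read a distance table written by [write_distances()]
#' @param path TSV path.
#' @return Tibble with `Inf` sentinels restored.
#' @export
read_distances <- function(path) {
  read_tsv_checked(path, c("species", "sample_a", "sample_b", "raw_jc69"),
                   readr::cols(species = "c", sample_a = "c", sample_b = "c",
                               .default = readr::col_double()))
}
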