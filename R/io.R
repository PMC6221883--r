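#' Read an OTU count table with sample metadata
#'
#' Reads a tab-separated count matrix (rows = samples, first column
#' `sample_id`) together with a CSV of per-sample metadata and returns a
#' validated [otu_table] object. Sample order follows the counts file.
#'
#' @param counts_path path to a TSV whose first column is `sample_id` and
#'   remaining columns are OTU counts (non-negative integers).
#' @param metadata_path path to a CSV keyed by `sample_id` with columns
#'   `life_stage` (`"adult"` or `"larva"`), `dam_id`, `sire_id`,
#'   `size_class`, `x`, `y` (the parentage, size and coordinate columns may
#'   be `NA` where not applicable).
#' @return an object of class `otu_table`; see [otu_table()].
#' @export
read_otu_table <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("counts TSV needs a sample_id column plus >= 1 OTU column")
  if (names(raw)[1L] != "sample_id") {
    stop("first column of the counts TSV must be 'sample_id' (rows = samples); ",
         "got '", names(raw)[1L], "' - transposed input is rejected, not auto-fixed")
  }
  sample_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad)) {
      stop("invalid count at sample '", sample_ids[bad[1L]], "', OTU '",
           colnames(mat)[j], "': '", raw[bad[1L], j + 1L],
           "' (counts must be non-negative integers)")
    }
  }
  counts <- matrix(as.integer(mat), nrow = nrow(mat),
                   dimnames = list(sample_ids, colnames(mat)))
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  otu_table(counts, metadata)
}

#' Construct a validated OTU table
#'
#' The central observable of the package: a non-negative integer count
#' matrix (samples x OTUs) bound to per-sample metadata. Larvae must carry a
#' dam identifier; adults must not carry parentage.
#'
#' @param counts integer matrix, rows = samples (named), columns = OTUs (named).
#' @param metadata data.frame with a `sample_id` column matching the rows of
#'   `counts`, plus `life_stage` and optionally `dam_id`, `sire_id`,
#'   `size_class`, `x`, `y`.
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `sample_ids`, `otu_ids`, `metadata` (metadata reordered to match rows).
#' @export
otu_table <- function(counts, metadata) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids in counts")
  if (any(counts < 0)) stop("negative counts are not allowed")
  storage.mode(counts) <- "integer"
  if (!"sample_id" %in% names(metadata)) stop("metadata must have a sample_id column")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  for (col in c("dam_id", "sire_id", "size_class", "x", "y"))
    if (!col %in% names(metadata)) metadata[[col]] <- NA
  if (!"life_stage" %in% names(metadata)) stop("metadata must have a life_stage column")
  if (!all(metadata$life_stage %in% c("adult", "larva")))
    stop("life_stage must be 'adult' or 'larva'")
  larv <- metadata$life_stage == "larva"
  if (any(larv & is.na(metadata$dam_id)))
    stop("every larva needs a non-missing dam_id; offending sample(s): ",
         paste(metadata$sample_id[larv & is.na(metadata$dam_id)], collapse = ", "))
  if (any(!larv & (!is.na(metadata$dam_id) | !is.na(metadata$sire_id))))
    stop("adults must have missing dam_id and sire_id")
  structure(list(counts = counts,
                 sample_ids = rownames(counts),
                 otu_ids = colnames(counts),
                 metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  life stages:", paste(names(table(x$metadata$life_stage)),
                              table(x$metadata$life_stage),
                              sep = "=", collapse = ", "), "\n")
  cat("  total reads:", sum(x$counts), "\n")
  invisible(x)
}

#' Write an OTU table to disk
#'
#' Inverse of [read_otu_table()]: writes `counts.tsv` (first column
#' `sample_id`) and `metadata.csv` such that reading them back reproduces
#' the object exactly.
#'
#' @param table an `otu_table`.
#' @param counts_path,metadata_path output file paths.
#' @return invisibly, the input table.
#' @export
write_otu_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(sample_id = table$sample_ids, table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(table$metadata, metadata_path, row.names = FALSE, na = "")
  invisible(table)
}

#' Read OTU representative sequences from FASTA
#'
#' @param path FASTA file with unique headers.
#' @return a named character vector (`sequence_set`): otu_id -> upper-case
#'   nucleotide string.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA: ", path)
  if (anyDuplicated(names(dna)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(dna)[duplicated(names(dna))]), collapse = ", "))
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA")
  sequence_set(seqs)
}

#' Construct a sequence set
#'
#' @param seqs named character vector of nucleotide strings over
#'   `A,C,G,T,N,-` (case-insensitive; stored upper-case).
#' @return the validated, upper-cased named vector with class `sequence_set`.
#' @export
sequence_set <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("sequence '", names(seqs)[bad][1L], "' has characters outside ACGTN-")
  structure(seqs, class = "sequence_set")
}

#' Write a sequence set to FASTA
#'
#' @param seqs a `sequence_set` (named character vector).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unclass(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a pedigree from CSV
#'
#' Expects columns `individual`, `dam`, `sire`; unknown parents are empty or
#' NA. Individuals are topologically sorted so parents precede offspring
#' (founders first); cycles are rejected.
#'
#' @param path CSV path.
#' @return a `pedigree` object; see [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual", "dam", "sire")
  if (!all(need %in% names(df)))
    stop("pedigree CSV needs columns: ", paste(need, collapse = ", "))
  for (col in c("dam", "sire")) df[[col]][df[[col]] %in% c("", "NA")] <- NA
  pedigree(df$individual, df$dam, df$sire)
}

#' Construct a validated, sorted pedigree
#'
#' Parents not listed as individuals are added as founders. The returned
#' records are topologically sorted (founders first, parents before
#' offspring); cyclic parentage is an error. Selfed offspring
#' (`dam == sire`) are permitted.
#'
#' @param individual,dam,sire character vectors; `NA` for unknown parents.
#' @return an object of class `pedigree`: a data.frame with columns
#'   `individual`, `dam`, `sire` in topological order.
#' @export
pedigree <- function(individual, dam, sire) {
  individual <- as.character(individual)
  dam <- as.character(dam); sire <- as.character(sire)
  if (anyDuplicated(individual))
    stop("duplicate individual id(s): ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  implicit <- setdiff(c(dam, sire), c(individual, NA))
  if (length(implicit)) {
    individual <- c(implicit, individual)
    dam <- c(rep(NA_character_, length(implicit)), dam)
    sire <- c(rep(NA_character_, length(implicit)), sire)
  }
  n <- length(individual)
  idx <- stats::setNames(seq_len(n), individual)
  # Kahn topological sort; founders (both parents unknown) drain first.
  parents <- cbind(ifelse(is.na(dam), NA_integer_, idx[dam]),
                   ifelse(is.na(sire), NA_integer_, idx[sire]))
  indeg <- rowSums(!is.na(parents))
  # self-parentage (own ancestor, length-1 cycle)
  if (any(parents == seq_len(n), na.rm = TRUE))
    stop("cycle in pedigree: individual listed as its own parent")
  children <- lapply(seq_len(n), function(i) which(parents[, 1] == i | parents[, 2] == i))
  order <- integer(0)
  queue <- which(indeg == 0)
  deg <- indeg
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      dec <- sum(parents[ch, ] == i, na.rm = TRUE)
      deg[ch] <- deg[ch] - dec
      if (deg[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("cycle in pedigree involving: ",
         paste(individual[setdiff(seq_len(n), order)], collapse = ", "))
  # founders first within the topological order
  founders <- is.na(dam[order]) & is.na(sire[order])
  order <- c(order[founders], order[!founders])
  out <- data.frame(individual = individual[order], dam = dam[order],
                    sire = sire[order], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$dam) & is.na(x$sire))
  selfed <- sum(!is.na(x$dam) & !is.na(x$sire) & x$dam == x$sire)
  cat("Pedigree:", nrow(x), "individuals (", founders, "founders,",
      nrow(x) - founders, "offspring,", selfed, "selfed )\n")
  invisible(x)
}

#' Write a pedigree to CSV
#'
#' @param ped a `pedigree`.
#' @param path output path; unknown parents written as empty fields.
#' @return invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' Bundles the analysis knobs shared across pipeline stages. The MCMC
#' defaults mirror the study protocol (1.5e6 iterations, thinning 50,
#' 10% burn-in) scaled to a desk default of 2e4 iterations; pass
#' `iterations = 1.5e6` to run at the study scale.
#'
#' @param q_grid non-negative diversity orders to profile over.
#' @param trait_q the order exported as the scalar heritability trait.
#' @param iterations,thinning,burn_in_fraction,prior_shape,prior_scale,seed
#'   Gibbs sampler settings; `burn_in_fraction` in `[0, 1)`.
#' @param permutations permutations for PERMANOVA / dispersion tests.
#' @param bh_alpha Benjamini-Hochberg significance level in (0, 1).
#' @param prevalence_threshold brood prevalence cut for network edges, (0, 1].
#' @return a list of class `run_config`.
#' @export
run_config <- function(q_grid = c(0, 1, 2, Inf), trait_q = 1,
                       iterations = 2e4, thinning = 50,
                       burn_in_fraction = 0.1,
                       prior_shape = 0.001, prior_scale = 0.001,
                       seed = 1L, permutations = 999,
                       bh_alpha = 0.05, prevalence_threshold = 0.5) {
  stopifnot(all(q_grid >= 0), burn_in_fraction >= 0, burn_in_fraction < 1,
            bh_alpha > 0, bh_alpha < 1,
            prevalence_threshold > 0, prevalence_threshold <= 1,
            permutations >= 1)
  structure(list(q_grid = q_grid, trait_q = trait_q,
                 iterations = iterations, thinning = thinning,
                 burn_in_fraction = burn_in_fraction,
                 prior_shape = prior_shape, prior_scale = prior_scale,
                 seed = as.integer(seed), permutations = as.integer(permutations),
                 bh_alpha = bh_alpha,
                 prevalence_threshold = prevalence_threshold),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(vals$q_grid))
    vals$q_grid <- vapply(vals$q_grid,
                          function(q) if (identical(q, "Inf")) Inf else as.numeric(q),
                          numeric(1))
  do.call(run_config, vals)
}
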