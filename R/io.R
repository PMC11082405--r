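# Readers and writers for the pipeline's external formats: FASTA genomes,
# target-site lists (VCF or 4/5-column TSV), background SNP tracks (VCF),
# per-phenotype GWAS summary tables (TSV) and the design report (TSV).

.REPORT_COLUMNS <- c(
  "site_id", "status", "fail_reason", "strand", "protospacer", "pam",
  "protospacer_start", "protospacer_end",
  "same_base_in_window", "gc_fraction", "repeat_count", "snp_count",
  "offtarget_score",
  "rank_same_base", "rank_gc", "rank_repeat", "rank_snp", "rank_offtarget",
  "rra_score", "is_best"
)

#' Read a reference genome from FASTA
#'
#' Loads all records into a [Biostrings::DNAStringSet], uppercased, with
#' multi-line records concatenated. Record names are taken up to the first
#' whitespace.
#'
#' @param path FASTA file (plain or gzipped).
#' @return a `DNAStringSet`, one entry per chromosome.
#' @export
readGenome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0L)
    stop("format error: FASTA file ", sQuote(path), " contains no records",
         call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("format error: duplicate FASTA record name(s): ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "), call. = FALSE)
  freq <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (any(bad > 0))
    stop("format error: genome contains letters outside {A,C,G,T,N} in: ",
         paste(names(genome)[bad > 0], collapse = ", "), call. = FALSE)
  genome
}

.siteId <- function(id, chrom, pos) {
  ifelse(is.na(id) | id %in% c("", "."), paste0(chrom, ":", pos), id)
}

#' Read target sites from VCF or TSV and validate against the genome
#'
#' Accepts a VCF (v4.x, plain or bgzipped; the first ALT allele is used) or
#' a headerless tab-separated list with columns chrom, 1-based position,
#' reference base, alternate base and optionally a site id (synthesized as
#' `"chrom:pos"` when absent). Every site is checked against the genome:
#' unknown chromosome, position beyond the chromosome end, and
#' reference-base mismatch are recorded per site in the `load_error` column
#' rather than silently dropped.
#'
#' @param path input file.
#' @param genome a `DNAStringSet` from [readGenome()].
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return data.frame with columns `site_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `load_error` (`NA` for valid sites).
#' @export
readSites <- function(path, genome, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.b?gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    sites <- data.frame(
      site_id = .siteId(fix[, "ID"], fix[, "CHROM"], fix[, "POS"]),
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]),
      ref = toupper(fix[, "REF"]),
      alt = toupper(vapply(strsplit(fix[, "ALT"], ",", fixed = TRUE),
                           `[`, character(1), 1L)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", comment.char = "#")
    if (ncol(raw) < 4L)
      stop("format error: site TSV needs >= 4 columns ",
           "(chrom, pos, ref, alt[, id])", call. = FALSE)
    id <- if (ncol(raw) >= 5L) raw[[5]] else NA_character_
    sites <- data.frame(
      site_id = .siteId(id, raw[[1]], raw[[2]]),
      chrom = raw[[1]], pos = as.integer(raw[[2]]),
      ref = toupper(raw[[3]]), alt = toupper(raw[[4]]),
      stringsAsFactors = FALSE
    )
  }
  sites$load_error <- NA_character_
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(sites))) {
    if (!sites$chrom[i] %in% names(genome)) {
      sites$load_error[i] <- "unknown_chromosome"
    } else if (is.na(sites$pos[i]) || sites$pos[i] < 1L ||
               sites$pos[i] > lens[[sites$chrom[i]]]) {
      sites$load_error[i] <- "position_out_of_range"
    } else {
      gbase <- as.character(Biostrings::subseq(
        genome[[match(sites$chrom[i], names(genome))]],
        sites$pos[i], sites$pos[i]))
      if (gbase != sites$ref[i]) {
        sites$load_error[i] <- sprintf("ref_mismatch(genome=%s)", gbase)
      } else if (sites$ref[i] == sites$alt[i]) {
        sites$load_error[i] <- "ref_equals_alt"
      }
    }
  }
  sites
}

#' Read a background SNP track from VCF
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [GenomicRanges::GRanges] of SNP positions (width-1 ranges).
#' @export
readSnpTrack <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L)
    return(GenomicRanges::GRanges())
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  GenomicRanges::GRanges(
    seqnames = fix[, "CHROM"],
    ranges = IRanges::IRanges(start = as.integer(fix[, "POS"]), width = 1L),
    snp_id = .siteId(fix[, "ID"], fix[, "CHROM"], fix[, "POS"])
  )
}

.GWAS_REQUIRED <- c("snp_id", "chrom", "pos", "beta_obs", "p_value",
                    "phi", "theta")

.readGwasFile <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.GWAS_REQUIRED, names(tab))
  if (length(missing))
    stop("format error in ", sQuote(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"phenotype_id" %in% names(tab))
    tab$phenotype_id <- rep(tools::file_path_sans_ext(basename(path)),
                            nrow(tab))
  keep <- c("snp_id", "chrom", "pos", "phenotype_id", "beta_obs", "p_value",
            "phi", "theta",
            intersect("effect_allele", names(tab)))
  tab[, keep, drop = FALSE]
}

#' Read GWAS summary statistics
#'
#' Reads one tab-separated summary table or a directory of them (one
#' phenotype per file). Required columns: `snp_id`, `chrom`, `pos`,
#' `beta_obs` (allelic substitution effect on the observed scale),
#' `p_value`, `phi` (case proportion) and `theta` (reference allele
#' frequency). `phenotype_id` is taken from the column when present,
#' otherwise from the file name. Rows with `phi` or `theta` outside (0,1)
#' or `p_value` outside \[0,1\] are rejected with a single warning counting
#' them.
#'
#' @param path a TSV file or a directory of `.tsv` files.
#' @return data.frame of validated GWAS records.
#' @export
readGwas <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  } else path
  if (length(files) == 0L)
    stop("format error: no GWAS .tsv files found under ", sQuote(path),
         call. = FALSE)
  gwas <- do.call(rbind, lapply(files, .readGwasFile))
  gwas$pos <- as.integer(gwas$pos)
  for (col in c("beta_obs", "p_value", "phi", "theta"))
    gwas[[col]] <- as.numeric(gwas[[col]])
  bad <- !is.finite(gwas$phi) | gwas$phi <= 0 | gwas$phi >= 1 |
         !is.finite(gwas$theta) | gwas$theta <= 0 | gwas$theta >= 1 |
         !is.finite(gwas$p_value) | gwas$p_value < 0 | gwas$p_value > 1
  if (any(bad))
    warning(sum(bad), " GWAS record(s) rejected: phi/theta outside (0,1) ",
            "or p_value outside [0,1]", call. = FALSE)
  gwas[!bad, , drop = FALSE]
}

#' Write the design report
#'
#' One row per (site, candidate); failed sites emit a single row with empty
#' candidate fields. Columns are fixed (see [readReport()]); numeric values
#' are written with the shortest decimal representation that parses back to
#' the identical double, so a read-write-read cycle is lossless.
#'
#' @param results data.frame with the report columns (from [designGuides()]).
#' @param path destination TSV.
#' @export
writeReport <- function(results, path) {
  missing <- setdiff(.REPORT_COLUMNS, names(results))
  if (length(missing))
    stop("report is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- results[, .REPORT_COLUMNS, drop = FALSE]
  for (col in c("gc_fraction", "offtarget_score", "rank_same_base", "rank_gc",
                "rank_repeat", "rank_snp", "rank_offtarget", "rra_score"))
    out[[col]] <- .formatNumber(out[[col]])
  out$is_best <- ifelse(is.na(out$is_best), NA, ifelse(out$is_best, "true", "false"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read a design report written by [writeReport()]
#'
#' @param path report TSV.
#' @return data.frame with the same columns and types as produced by
#'   [designGuides()].
#' @export
readReport <- function(path) {
  rep <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  missing <- setdiff(.REPORT_COLUMNS, names(rep))
  if (length(missing))
    stop("format error: report is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  blankToNA <- function(x) ifelse(nzchar(x), x, NA_character_)
  for (col in c("strand", "protospacer", "pam")) rep[[col]] <- blankToNA(rep[[col]])
  for (col in c("protospacer_start", "protospacer_end", "same_base_in_window",
                "repeat_count", "snp_count"))
    rep[[col]] <- as.integer(blankToNA(rep[[col]]))
  for (col in c("gc_fraction", "offtarget_score", "rank_same_base", "rank_gc",
                "rank_repeat", "rank_snp", "rank_offtarget", "rra_score"))
    rep[[col]] <- as.numeric(blankToNA(rep[[col]]))
  rep$is_best <- c("true" = TRUE, "false" = FALSE)[blankToNA(rep$is_best)]
  names(rep$is_best) <- NULL
  rep
}
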