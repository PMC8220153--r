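# Reading, writing and harmonizing GWAS summary statistics.
#
# A sumstat table is a plain data.frame with canonical columns
#   snp, chr, pos, effect_allele, other_allele, beta, se, pvalue, n
# carrying the trait label and sex stratum as attributes.  Effects are
# per-allele marginal associations: SD units of the trait for quantitative
# exposures, log-odds for binary outcomes.

SUMSTAT_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "beta", "se", "pvalue", "n")

# Case-insensitive header aliases seen in common GWAS distributions; a user
# dialect (canonical -> file column) takes precedence.
.default_aliases <- list(
  snp           = c("snp", "rsid", "rs_id", "markername", "marker", "snpid", "variant_id"),
  chr           = c("chr", "chrom", "chromosome"),
  pos           = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "allele1", "ea", "alt"),
  other_allele  = c("other_allele", "a2", "allele2", "oa", "nea", "ref"),
  beta          = c("beta", "b", "effect", "beta_hat"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  pvalue        = c("pvalue", "p", "pval", "p_value"),
  n             = c("n", "samplesize", "n_total", "sample_size")
)

#' Construct a summary-statistics table
#'
#' Validates and classes a data.frame of per-SNP marginal associations for
#' one trait in one sex stratum.
#'
#' @param df Data frame with columns `snp`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, `n`.
#' @param trait_label Character scalar naming the trait.
#' @param stratum One of `"female"`, `"male"`, `"combined"`.
#' @return A `sumstat_table` (data.frame subclass).
#' @export
sumstat_table <- function(df, trait_label = "trait",
                          stratum = c("combined", "female", "male")) {
  stratum <- match.arg(stratum)
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols)) {
    stop_sexmr("missing required column(s): ",
               paste(missing_cols, collapse = ", "),
               class = "sexmr_format_error")
  }
  df <- as.data.frame(df)[SUMSTAT_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  dup <- unique(df$snp[duplicated(df$snp)])
  if (length(dup)) {
    stop_sexmr("duplicate snp id(s): ", paste(dup, collapse = ", "),
               class = "sexmr_format_error")
  }
  if (any(df$se <= 0, na.rm = TRUE)) {
    stop_sexmr("standard errors must be strictly positive",
               class = "sexmr_domain_error")
  }
  # clamp p-value underflow so records keep the open-unit-interval contract
  df$pvalue <- pmin(pmax(df$pvalue, .Machine$double.xmin), 1)
  rownames(df) <- NULL
  structure(df, trait_label = trait_label, stratum = stratum,
            class = c("sumstat_table", "data.frame"))
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Columns are resolved case-insensitively against built-in header aliases;
#' nonstandard headers can be mapped with `dialect` (a named list or vector,
#' canonical name -> file column name).  Rows with missing beta or standard
#' error are dropped with a logged count; rows whose alleles are not single
#' A/C/G/T nucleotides (indels, multi-allelic codes) are likewise dropped
#' with a warning.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dialect Optional named mapping from canonical column names to the
#'   file's column names.
#' @inheritParams sumstat_table
#' @return A [sumstat_table()].
#' @export
read_sumstats <- function(path, dialect = NULL, trait_label = "trait",
                          stratum = c("combined", "female", "male")) {
  stratum <- match.arg(stratum)
  if (!file.exists(path)) {
    stop_sexmr("file not found: ", path, class = "sexmr_io_error")
  }
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(raw))
  resolve <- function(canon) {
    if (!is.null(dialect) && canon %in% names(dialect)) {
      hit <- which(lower == tolower(dialect[[canon]]))
    } else {
      hit <- which(lower %in% .default_aliases[[canon]])
    }
    if (length(hit) == 0) {
      stop_sexmr("cannot resolve required column '", canon,
                 "' in ", path, class = "sexmr_format_error")
    }
    hit[1]
  }
  idx <- vapply(SUMSTAT_COLS, resolve, integer(1))
  df <- raw[idx]
  names(df) <- SUMSTAT_COLS
  for (col in c("pos", "beta", "se", "pvalue", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  keep <- !is.na(df$beta) & !is.na(df$se)
  if (any(!keep)) {
    sexmr_log("dropped ", sum(!keep), " row(s) with missing beta or se")
    df <- df[keep, , drop = FALSE]
  }
  snv <- grepl("^[ACGTacgt]$", df$effect_allele) &
    grepl("^[ACGTacgt]$", df$other_allele)
  if (any(!snv)) {
    warning(sum(!snv), " row(s) with non-SNV alleles (indels?) dropped",
            call. = FALSE)
    df <- df[snv, , drop = FALSE]
  }
  sumstat_table(df, trait_label = trait_label, stratum = stratum)
}

#' Write a summary-statistics table to a tab-separated file
#'
#' Uses full precision so that a read/write round trip reproduces the table
#' exactly.
#'
#' @param table A [sumstat_table()].
#' @param path Output path.
#' @export
write_sumstats <- function(table, path) {
  if (!inherits(table, "sumstat_table")) table <- sumstat_table(table)
  if (nrow(table) == 0) {
    stop_sexmr("refusing to write an empty summary-statistics table",
               class = "sexmr_domain_error")
  }
  out <- as.data.frame(table)
  for (col in c("beta", "se", "pvalue")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop_sexmr("cannot write ", path, ": ",
                                   conditionMessage(e),
                                   class = "sexmr_io_error")
  )
  invisible(path)
}

#' Construct an instrument set
#'
#' An ordered set of rsIDs selected as instrumental variables from one
#' stratum, together with the selection threshold used.
#'
#' @param snp_ids Character vector of rsIDs (non-empty, no duplicates).
#' @param source_stratum Stratum the instruments were selected in.
#' @param selection_threshold P-value threshold used for selection
#'   (genome-wide 5e-8 for real data).
#' @return An `instrument_set` (character vector with attributes).
#' @export
instrument_set <- function(snp_ids,
                           source_stratum = c("combined", "female", "male"),
                           selection_threshold = 5e-8) {
  source_stratum <- match.arg(source_stratum)
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) == 0) {
    stop_sexmr("instrument set must be non-empty", class = "sexmr_domain_error")
  }
  if (anyDuplicated(snp_ids)) {
    stop_sexmr("instrument set contains duplicated ids",
               class = "sexmr_domain_error")
  }
  structure(snp_ids, source_stratum = source_stratum,
            selection_threshold = selection_threshold,
            class = "instrument_set")
}

#' Read an instrument set from a plain-text file (one rsID per line)
#' @inheritParams instrument_set
#' @param path Path to a text file with one rsID per line.
#' @return An [instrument_set()].
#' @export
read_instruments <- function(path,
                             source_stratum = c("combined", "female", "male"),
                             selection_threshold = 5e-8) {
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  instrument_set(trimws(ids), source_stratum = source_stratum,
                 selection_threshold = selection_threshold)
}

new_harmonized <- function(df, exclusions = list()) {
  rownames(df) <- NULL
  structure(df, exclusions = exclusions,
            class = c("harmonized_instruments", "data.frame"))
}

#' Align exposure and outcome summary statistics on a shared effect allele
#'
#' For each instrument present in both tables the outcome effect is
#' re-expressed on the exposure's effect allele: identical allele pairs are
#' kept as-is, swapped pairs (effect/other exchanged) have the outcome beta
#' sign-flipped, and inconsistent pairs are excluded.  Instruments absent
#' from the outcome table are excluded.  Allele comparison is
#' case-insensitive.  Strand-ambiguous (A/T, C/G) palindromic SNPs are kept
#' when alleles match exactly unless `drop_palindromic = TRUE`.
#'
#' @param exposure,outcome [sumstat_table()]s for the exposure and outcome.
#' @param ivs An [instrument_set()] (or character vector of rsIDs).
#' @param drop_palindromic Drop strand-ambiguous A/T and C/G SNPs entirely.
#' @return A `harmonized_instruments` data.frame with columns `snp`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `pvalue_y`; exclusion counts by
#'   reason are attached as attribute `exclusions`.
#' @export
harmonize <- function(exposure, outcome, ivs, drop_palindromic = FALSE) {
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop_sexmr("exposure and outcome tables must be non-empty",
               class = "sexmr_domain_error")
  }
  ids <- as.character(ivs)
  ex <- exposure[match(ids, exposure$snp), , drop = FALSE]
  missing_exposure <- ids[is.na(ex$snp)]
  ids <- setdiff(ids, missing_exposure)
  ex <- exposure[match(ids, exposure$snp), , drop = FALSE]
  ou <- outcome[match(ids, outcome$snp), , drop = FALSE]

  in_outcome <- !is.na(ou$snp)
  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)

  same <- in_outcome & ea_x == ea_y & oa_x == oa_y
  swapped <- in_outcome & ea_x == oa_y & oa_x == ea_y
  inconsistent <- in_outcome & !same & !swapped
  palindromic <- (ea_x == "A" & oa_x == "T") | (ea_x == "T" & oa_x == "A") |
    (ea_x == "C" & oa_x == "G") | (ea_x == "G" & oa_x == "C")
  dropped_pal <- drop_palindromic & palindromic & (same | swapped)

  keep <- (same | swapped) & !dropped_pal
  sign <- ifelse(swapped, -1, 1)

  exclusions <- list(
    missing_from_exposure = missing_exposure,
    missing_from_outcome = ids[!in_outcome],
    allele_inconsistent = ids[inconsistent],
    palindromic_dropped = ids[dropped_pal & !is.na(dropped_pal)]
  )
  n_excl <- vapply(exclusions, length, integer(1))
  if (sum(n_excl) > 0) {
    sexmr_log("harmonize exclusions: ",
              paste(names(n_excl)[n_excl > 0], n_excl[n_excl > 0],
                    sep = "=", collapse = ", "))
  }
  if (!any(keep)) {
    stop_sexmr("no instruments survive harmonization; MR is not possible",
               class = "sexmr_empty_instruments_error")
  }
  df <- data.frame(
    snp = ids[keep],
    beta_x = ex$beta[keep],
    se_x = ex$se[keep],
    beta_y = sign[keep] * ou$beta[keep],
    se_y = ou$se[keep],
    pvalue_y = ou$pvalue[keep],
    stringsAsFactors = FALSE
  )
  new_harmonized(df, exclusions)
}

#' Exclude instruments that are themselves associated with the outcome
#'
#' Conservative pleiotropy guard: removes every instrument whose outcome
#' p-value is Bonferroni-significant (`pvalue_y * k < alpha`, with `k` the
#' number of instruments entering the filter).
#'
#' @param h A [harmonize()]d instrument set.
#' @param alpha Significance level for the Bonferroni-corrected screen.
#' @return The filtered `harmonized_instruments`; removed ids are logged
#'   and recorded in the `exclusions` attribute.
#' @export
qc_filter_outcome_associated <- function(h, alpha = 0.05) {
  k <- nrow(h)
  if (k < 1) stop_sexmr("no instruments to filter", class = "sexmr_domain_error")
  remove <- h$pvalue_y * k < alpha
  if (any(remove)) {
    sexmr_log("outcome-association QC removed ", sum(remove), " of ", k,
              " instrument(s): ", paste(h$snp[remove], collapse = ", "))
  }
  if (all(remove)) {
    stop_sexmr("all instruments removed by outcome-association QC",
               class = "sexmr_empty_instruments_error")
  }
  exclusions <- attr(h, "exclusions") %||% list()
  exclusions$outcome_associated <- h$snp[remove]
  new_harmonized(as.data.frame(h)[!remove, , drop = FALSE], exclusions)
}
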