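#' Canonical chromosome rank
#'
#' Orders chromosome labels numerically with X placed after 22 (rank 23) and Y
#' after X; non-numeric synthetic labels are ranked after all numeric ones in
#' alphabetical order. A leading "chr" prefix is ignored.
#'
#' @param chrom character vector of chromosome labels.
#' @return numeric rank usable for sorting.
#' @export
chrom_rank <- function(chrom) {
    lab <- sub("^chr", "", as.character(chrom))
    r <- suppressWarnings(as.numeric(lab))
    r[lab == "X"] <- 23
    r[lab == "Y"] <- 24
    if (anyNA(r)) {
        extra <- sort(unique(lab[is.na(r)]))
        r[is.na(r)] <- 24 + match(lab[is.na(r)], extra)
    }
    r
}

#' Construct a validated probe panel
#'
#' A probe panel describes the array design: one row per probe with a unique
#' id, a chromosome label, a 1-based genomic position and a flag marking
#' probes added to enrich the design at cancer-gene loci (these are excluded
#' from breakpoint analyses to keep probe spacing even).
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos` and optionally
#'   `is_enrichment` (defaults to `FALSE`).
#' @return the validated data.frame with class `probe_panel` prepended.
#' @export
probe_panel <- function(df) {
    need <- c("probe_id", "chrom", "pos")
    if (!all(need %in% names(df)))
        stop("probe panel needs columns: ", paste(need, collapse = ", "))
    if (is.null(df$is_enrichment)) df$is_enrichment <- FALSE
    df$probe_id <- as.character(df$probe_id)
    df$chrom <- as.character(df$chrom)
    df$pos <- as.integer(df$pos)
    df$is_enrichment <- as.logical(df$is_enrichment)
    if (anyNA(df$pos) || any(df$pos < 1))
        stop("probe positions must be positive 1-based integers")
    if (anyDuplicated(df$probe_id))
        stop("probe_ids not unique: ", df$probe_id[anyDuplicated(df$probe_id)])
    o <- order(chrom_rank(df$chrom), df$pos)
    if (any(o != seq_len(nrow(df)))) {
        bad <- df$probe_id[which(o != seq_len(nrow(df)))[1]]
        stop("panel not sorted by (chromosome, position); first offending probe: ",
             bad)
    }
    rownames(df) <- NULL
    class(df) <- c("probe_panel", "data.frame")
    df
}

#' Construct a copy-number cohort
#'
#' Couples a probe panel with a probe x sample matrix of log2 tumor/normal
#' ratios. Row order must match the panel's probe order.
#'
#' @param panel a [probe_panel()].
#' @param ratios numeric matrix, probes in rows (panel order), samples in
#'   columns; column names are the sample ids.
#' @return object of class `cna_cohort`.
#' @export
cna_cohort <- function(panel, ratios) {
    panel <- if (inherits(panel, "probe_panel")) panel else probe_panel(panel)
    ratios <- as.matrix(ratios)
    if (nrow(ratios) != nrow(panel))
        stop("ratio matrix has ", nrow(ratios), " rows but panel has ",
             nrow(panel), " probes")
    if (is.null(colnames(ratios)))
        stop("ratio matrix must carry sample ids as column names")
    if (any(!is.finite(ratios)))
        stop("ratio matrix contains non-finite values; missing log2 ratios ",
             "are not supported")
    rownames(ratios) <- panel$probe_id
    structure(list(panel = panel, ratios = ratios,
                   samples = colnames(ratios)),
              class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
    cat("cna_cohort:", nrow(x$panel), "probes x", length(x$samples),
        "samples on", length(unique(x$panel$chrom)), "chromosomes\n")
    invisible(x)
}

#' Drop enrichment probes from a cohort
#'
#' Returns the cohort restricted to evenly spaced backbone probes; used before
#' breakpoint analysis so the per-probe breakage null is not distorted by the
#' locally densified cancer-gene probes.
#'
#' @param cohort a [cna_cohort()].
#' @return a `cna_cohort` without enrichment probes.
#' @export
drop_enrichment_probes <- function(cohort) {
    stopifnot(inherits(cohort, "cna_cohort"))
    keep <- !cohort$panel$is_enrichment
    panel <- cohort$panel[keep, , drop = FALSE]
    rownames(panel) <- NULL
    class(panel) <- c("probe_panel", "data.frame")
    cna_cohort(panel, cohort$ratios[keep, , drop = FALSE])
}

#' Construct a clinical table
#'
#' @param df data.frame with columns `sample_id`, `stage` ("II"/"III"),
#'   `relapse` (logical), `dfs_time` (months, > 0), `event` (logical),
#'   `adjuvant` (logical).
#' @return validated data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
    need <- c("sample_id", "stage", "relapse", "dfs_time", "event", "adjuvant")
    if (!all(need %in% names(df)))
        stop("clinical table needs columns: ", paste(need, collapse = ", "))
    df$sample_id <- as.character(df$sample_id)
    df$stage <- as.character(df$stage)
    df$relapse <- as.logical(df$relapse)
    df$event <- as.logical(df$event)
    df$adjuvant <- as.logical(df$adjuvant)
    df$dfs_time <- as.numeric(df$dfs_time)
    if (!all(df$stage %in% c("II", "III")))
        stop("stage must be II or III")
    if (any(df$dfs_time <= 0))
        stop("dfs_time must be positive")
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
    rownames(df) <- NULL
    class(df) <- c("clinical_table", "data.frame")
    df
}

# internal: check a sample set against a cohort, reporting the set difference
check_samples <- function(have, want, what = "clinical table") {
    miss <- setdiff(want, have)
    extra <- setdiff(have, want)
    if (length(miss) || length(extra))
        stop("sample mismatch with ", what,
             if (length(miss)) paste0("; missing: ",
                                      paste(miss, collapse = ", ")) else "",
             if (length(extra)) paste0("; unexpected: ",
                                       paste(extra, collapse = ", ")) else "")
    invisible(TRUE)
}
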