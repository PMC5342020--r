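#' Read a probe panel TSV
#'
#' Expected columns: `probe_id`, `chrom`, `pos` (1-based), optional
#' `is_enrichment`. Probes must be sorted by (chromosome, position); the
#' first offending probe is named otherwise.
#'
#' @param path TSV file.
#' @return a [probe_panel()].
#' @export
read_probe_panel <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    probe_panel(df)
}

#' @rdname read_probe_panel
#' @param panel a [probe_panel()] to write.
#' @export
write_probe_panel <- function(panel, path) {
    write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a probe x sample log2-ratio matrix
#'
#' First column `probe_id`, remaining columns one per sample. Probe ids must
#' match the panel exactly and in order; values must be numeric and finite.
#'
#' @param path TSV file.
#' @param panel the matching [probe_panel()].
#' @return a [cna_cohort()].
#' @export
read_ratio_matrix <- function(path, panel) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "probe_id")
        stop("first column of the ratio matrix must be probe_id")
    if (!identical(df$probe_id, panel$probe_id))
        stop("ratio-matrix probes do not match the panel (order included)")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric log2 ratios in ", path)
    cna_cohort(panel, m)
}

#' @rdname read_ratio_matrix
#' @param cohort a [cna_cohort()] to write.
#' @export
write_ratio_matrix <- function(cohort, path) {
    df <- data.frame(probe_id = cohort$panel$probe_id,
                     cohort$ratios, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene models from BED
#'
#' BED is 0-based half-open; internal gene models are 1-based inclusive, so
#' `chr1 99 200 GENE` becomes start 100, end 200. Gene names must be unique.
#'
#' @param path BED file (>= 4 columns, no header).
#' @return data.frame (gene_name, chrom, start, end), sorted.
#' @export
read_gene_bed <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("gene BED needs >= 4 columns (chrom start end name)")
    genes <- data.frame(gene_name = as.character(df[[4]]),
                        chrom = sub("^chr", "", as.character(df[[1]])),
                        start = as.integer(df[[2]]) + 1L,
                        end = as.integer(df[[3]]),
                        stringsAsFactors = FALSE)
    if (any(genes$start > genes$end)) stop("gene with start > end in ", path)
    if (anyDuplicated(genes$gene_name)) stop("duplicate gene names in ", path)
    genes[order(chrom_rank(genes$chrom), genes$start), , drop = FALSE]
}

#' Read / write the clinical table
#'
#' @param path TSV with columns sample_id, stage, relapse, dfs_time, event,
#'   adjuvant.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
    clinical_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param clinical a [clinical_table()] to write.
#' @export
write_clinical <- function(clinical, path) {
    write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read variant records
#'
#' TSV with columns sample_id, gene, vaf, consequence, known_polymorphism.
#'
#' @param path TSV file.
#' @return validated data.frame of variant records.
#' @export
read_variants <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "gene", "vaf", "consequence", "known_polymorphism")
    if (!all(need %in% names(df)))
        stop("variant file needs columns: ", paste(need, collapse = ", "))
    df$vaf <- as.numeric(df$vaf)
    df$known_polymorphism <- as.logical(df$known_polymorphism)
    if (anyNA(df$vaf) || any(df$vaf < 0) || any(df$vaf > 1))
        stop("vaf must be numeric in [0, 1]")
    if (!all(df$consequence %in% c("synonymous", "non_synonymous")))
        stop("consequence must be synonymous or non_synonymous")
    df
}

#' Write / read segments in SEG format
#'
#' Standard SEG columns (ID, chrom, loc.start, loc.end, num.mark, seg.mean),
#' coordinates 1-based inclusive basepairs taken from the panel positions of
#' the boundary probes; one row per segment, means at 6 decimals.
#'
#' @param seg_cohort a `seg_cohort`.
#' @param path output file.
#' @export
write_seg <- function(seg_cohort, path) {
    stopifnot(inherits(seg_cohort, "seg_cohort"))
    s <- seg_cohort$segments
    df <- data.frame(ID = s$sample, chrom = s$chrom,
                     loc.start = seg_cohort$panel$pos[s$start_probe],
                     loc.end = seg_cohort$panel$pos[s$end_probe],
                     num.mark = s$num_probes,
                     seg.mean = sprintf("%.6f", s$seg_mean))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_seg
#' @param panel optional [probe_panel()]; when given, basepair coordinates
#'   are mapped back to panel probe indices.
#' @return data.frame of segments; with a panel, including `start_probe` /
#'   `end_probe` global probe indices.
#' @export
read_seg <- function(path, panel = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
    if (!all(need %in% names(df)))
        stop("SEG file needs columns: ", paste(need, collapse = ", "))
    df$seg.mean <- as.numeric(df$seg.mean)
    df$chrom <- as.character(df$chrom)
    if (!is.null(panel)) {
        key <- paste(panel$chrom, panel$pos)
        df$start_probe <- match(paste(df$chrom, df$loc.start), key)
        df$end_probe <- match(paste(df$chrom, df$loc.end), key)
        if (anyNA(df$start_probe) || anyNA(df$end_probe))
            stop("SEG coordinates not found in panel")
    }
    df
}

#' Write a simulated cohort (with ground-truth sidecars) to a directory
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_probe_panel(sim$cohort$panel, file.path(dir, "probe_panel.tsv"))
    write_ratio_matrix(sim$cohort, file.path(dir, "ratios.tsv"))
    write_clinical(sim$clinical, file.path(dir, "clinical.tsv"))
    write.table(data.frame(sample_id = rownames(sim$mutations),
                           sim$mutations, check.names = FALSE),
                file.path(dir, "mutations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sim$truth$segments, file.path(dir, "truth_segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bp <- data.frame(
        sample = rep(names(sim$truth$breakpoints),
                     lengths(sim$truth$breakpoints)),
        probe_index = unlist(sim$truth$breakpoints, use.names = FALSE))
    write.table(bp, file.path(dir, "truth_breakpoints.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a cohort directory written by [write_sim_cohort()]
#'
#' Validates that the ratio matrix and clinical table cover the same
#' samples, reporting the set difference otherwise.
#'
#' @param dir directory with probe_panel.tsv, ratios.tsv, clinical.tsv and
#'   optionally mutations.tsv.
#' @return list(cohort, clinical, mutations).
#' @export
read_cohort_dir <- function(dir) {
    panel <- read_probe_panel(file.path(dir, "probe_panel.tsv"))
    cohort <- read_ratio_matrix(file.path(dir, "ratios.tsv"), panel)
    clinical <- read_clinical(file.path(dir, "clinical.tsv"))
    check_samples(clinical$sample_id, cohort$samples, "clinical table")
    mut <- NULL
    mpath <- file.path(dir, "mutations.tsv")
    if (file.exists(mpath)) {
        md <- read.delim(mpath, stringsAsFactors = FALSE,
                         check.names = FALSE)
        mut <- as.matrix(md[, -1, drop = FALSE])
        rownames(mut) <- md$sample_id
        storage.mode(mut) <- "integer"
    }
    list(cohort = cohort, clinical = clinical, mutations = mut)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. from [cluster_samples()]).
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}
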