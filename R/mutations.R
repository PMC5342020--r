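#' Build the sample x gene mutation matrix from variant records
#'
#' A gene is called mutated in a sample when at least one of its variant
#' records survives all three filters: variant allele fraction of at least
#' 0.20 (strict `>=`), not a synonymous change, and not a known
#' polymorphism. Samples without surviving records get an all-zero row.
#'
#' @param records data.frame of variant records with columns `sample_id`,
#'   `gene`, `vaf` (fraction in \[0, 1\]), `consequence`
#'   ("synonymous"/"non_synonymous"), `known_polymorphism` (logical).
#' @param samples character vector of cohort sample ids (row universe).
#' @param genes character vector of genes (column universe); defaults to
#'   the genes present in `records`.
#' @param vaf_min minimum variant allele fraction.
#' @return binary integer matrix, samples x genes.
#' @export
call_mutations <- function(records, samples,
                           genes = sort(unique(records$gene)),
                           vaf_min = 0.20) {
    if (nrow(records)) {
        if (any(records$vaf < 0 | records$vaf > 1))
            stop("vaf must lie in [0, 1]")
        unknown <- setdiff(records$sample_id, samples)
        if (length(unknown))
            stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    }
    m <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
    keep <- records$vaf >= vaf_min &
        records$consequence != "synonymous" &
        !records$known_polymorphism &
        records$gene %in% genes
    hits <- unique(records[keep, c("sample_id", "gene")])
    if (nrow(hits)) m[cbind(hits$sample_id, hits$gene)] <- 1L
    m
}

#' Add pathway-combination columns to a mutation matrix
#'
#' Appends logical-OR columns over gene sets, e.g. the MAPK pathway
#' (KRAS/NRAS/BRAF) and APC-or-MAPK. Idempotent: recomputed columns replace
#' existing ones of the same name.
#'
#' @param mut binary sample x gene matrix.
#' @param gene_sets named list of character vectors; set members may
#'   reference earlier derived columns.
#' @return the matrix with derived columns appended.
#' @export
pathway_combine <- function(mut,
                            gene_sets = list(
                                MAPK = c("KRAS", "NRAS", "BRAF"),
                                APC_or_MAPK = c("APC", "MAPK"))) {
    if (!length(gene_sets)) stop("gene_sets must not be empty")
    for (nm in names(gene_sets)) {
        gs <- gene_sets[[nm]]
        if (!length(gs)) stop("empty gene set: ", nm)
        miss <- setdiff(gs, colnames(mut))
        if (length(miss))
            stop("gene set ", nm, " references unknown gene(s): ",
                 paste(miss, collapse = ", "))
        col <- as.integer(rowSums(mut[, gs, drop = FALSE]) > 0)
        mut <- mut[, setdiff(colnames(mut), nm), drop = FALSE]
        mut <- cbind(mut, col)
        colnames(mut)[ncol(mut)] <- nm
    }
    mut
}

#' Pairwise mutation co-occurrence / mutual-exclusivity tests
#'
#' For each gene pair, builds the 2x2 mutation cross-table and applies the
#' two-sided Fisher exact test; direction is reported as co-occurrence when
#' the sample odds ratio exceeds 1 and exclusivity when below 1.
#'
#' @param mut binary sample x gene matrix.
#' @param pairs two-column character matrix (or data.frame) of gene pairs;
#'   defaults to all pairs of matrix columns.
#' @return data.frame (gene1, gene2, n11, n10, n01, n00, odds_ratio, p,
#'   direction, flagged).
#' @export
cooccurrence_tests <- function(mut, pairs = NULL) {
    genes <- colnames(mut)
    if (is.null(pairs)) {
        idx <- utils::combn(length(genes), 2)
        pairs <- cbind(genes[idx[1, ]], genes[idx[2, ]])
    }
    pairs <- as.matrix(pairs)
    out <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
        if (!all(c(g1, g2) %in% genes))
            stop("unknown gene in pair: ", g1, "/", g2)
        a <- mut[, g1]; b <- mut[, g2]
        tab <- matrix(c(sum(a & b), sum(a & !b),
                        sum(!a & b), sum(!a & !b)), 2, 2)
        ft <- fisher_exact(tab)
        out[[i]] <- data.frame(
            gene1 = g1, gene2 = g2,
            n11 = tab[1, 1], n10 = tab[2, 1], n01 = tab[1, 2],
            n00 = tab[2, 2],
            odds_ratio = ft$odds_ratio, p = ft$p,
            direction = if (ft$flagged) NA_character_
                        else if (ft$odds_ratio > 1) "co-occurrence"
                        else if (ft$odds_ratio < 1) "exclusivity"
                        else "independent",
            flagged = ft$flagged, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Export a mutation matrix in oncoprint layout
#'
#' Writes one row per gene and one column per sample with values {0, 1};
#' genes are ordered by descending mutation frequency (then name), samples
#' by descending mutation burden (then id), so the output is canonical
#' regardless of input order.
#'
#' @param mut binary sample x gene matrix.
#' @param path optional TSV output path.
#' @return the reordered gene x sample matrix, invisibly when written.
#' @export
oncoprint_export <- function(mut, path = NULL) {
    if (!nrow(mut) || !ncol(mut)) stop("mutation matrix is empty")
    gene_order <- order(-colSums(mut), colnames(mut))
    samp_order <- order(-rowSums(mut), rownames(mut))
    out <- t(mut[samp_order, gene_order, drop = FALSE])
    if (!is.null(path)) {
        df <- data.frame(gene = rownames(out), out, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(out))
    }
    out
}
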