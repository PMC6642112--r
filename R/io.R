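#' @importFrom data.table fread fwrite dcast as.data.table
NULL

#' Read a single-cell expression matrix with labels
#'
#' Accepts either a dense TSV (first column = gene id, remaining columns
#' = cells) or a sparse triplet TSV (gene, cell, value; absent entries
#' are zero), plus a two-column cell / cell-type label TSV, and returns
#' the `SingleCellExperiment` consumed by [toCPM()] / [buildProfile()].
#'
#' @param exprFile expression TSV path.
#' @param labelsFile two-column TSV (cell id, cell type).
#' @param unit expression unit (`"count"`, `"UMI"`, `"CPM"`, `"RPKM"`,
#'   `"TPM"`).
#' @param format `"auto"` (default; triplet when exactly 3 columns and
#'   the third is the only numeric one), `"dense"` or `"triplet"`.
#' @return A `SingleCellExperiment`.
#' @export
readExpression <- function(exprFile, labelsFile,
                           unit = c("count", "UMI", "CPM", "RPKM", "TPM"),
                           format = c("auto", "dense", "triplet")) {
    unit <- match.arg(unit)
    format <- match.arg(format)
    dt <- fread(exprFile, header = TRUE)
    if (format == "auto")
        format <- if (ncol(dt) == 3 && !is.numeric(dt[[2]]) &&
                      is.numeric(dt[[3]])) "triplet" else "dense"
    if (format == "triplet") {
        names(dt) <- c("gene", "cell", "value")
        wide <- dcast(dt, gene ~ cell, value.var = "value", fill = 0)
        m <- as.matrix(wide, rownames = "gene")
    } else {
        m <- as.matrix(dt, rownames = 1)
    }
    lab <- fread(labelsFile, header = TRUE)
    rawExpression(m, setNames(as.character(lab[[2]]),
                              as.character(lab[[1]])), unit = unit)
}

#' Read / write a cell-type profile TSV
#'
#' The profile layout is `GENE`, one column per cell type, and a final
#' `Average` column holding the per-gene mean over the cell-type
#' columns (the conditioning covariate). `readProfile()` accepts files
#' without the `Average` column and recomputes it.
#'
#' @param file TSV path.
#' @param datasetId dataset id; defaults to the file name without
#'   extension.
#' @param species `"human"`, `"mouse"` or `"other"`.
#' @return A [CellTypeProfile-class].
#' @export
readProfile <- function(file, datasetId = NULL,
                        species = c("other", "human", "mouse")) {
    species <- match.arg(species)
    if (is.null(datasetId))
        datasetId <- sub("\\.[^.]*$", "", basename(file))
    dt <- fread(file, header = TRUE)
    m <- as.matrix(dt, rownames = 1)
    avg <- NULL
    if ("Average" %in% colnames(m)) {
        avg <- m[, "Average"]
        m <- m[, setdiff(colnames(m), "Average"), drop = FALSE]
    }
    CellTypeProfile(m, average = avg, datasetId = datasetId,
                    species = species)
}

#' @param profile a [CellTypeProfile-class].
#' @rdname readProfile
#' @export
writeProfile <- function(profile, file) {
    dt <- data.table::data.table(GENE = rownames(profile))
    E <- exprValues(profile)
    for (ct in colnames(E)) dt[[ct]] <- E[, ct]
    dt$Average <- unname(avgExpr(profile))
    fwrite(dt, file, sep = "\t")
    invisible(file)
}

#' Read gene-based association statistics
#'
#' Accepts the gene-analysis output dialect (columns GENE, CHR, START,
#' STOP, NSNPS, NPARAM, N, ZSTAT, P) or any TSV with a GENE column plus
#' ZSTAT/Z or P. Z-scores are taken from ZSTAT/Z when present, otherwise
#' probit-transformed from P via [zFromP()]. Gene length and log length
#' (from a LENGTH column or STOP - START + 1) are attached as default
#' technical confounders when available.
#'
#' @param file TSV path.
#' @param traitId trait id; defaults to the file name without extension.
#' @param geneCorrFile optional square gene-gene correlation TSV
#'   (header + first column = gene ids).
#' @return A [GeneStats-class].
#' @export
readGeneStats <- function(file, traitId = NULL, geneCorrFile = NULL) {
    if (is.null(traitId))
        traitId <- sub("\\.[^.]*$", "", basename(file))
    dt <- fread(file, header = TRUE)
    names(dt) <- toupper(names(dt))
    if (!"GENE" %in% names(dt))
        stop("gene statistics file needs a GENE column")
    genes <- as.character(dt$GENE)
    if (anyDuplicated(genes))
        stop("duplicated gene ids in ", file)
    z <- if ("ZSTAT" %in% names(dt)) dt$ZSTAT
         else if ("Z" %in% names(dt)) dt$Z
         else if ("P" %in% names(dt)) zFromP(dt$P)
         else stop("gene statistics file needs a ZSTAT, Z or P column")
    len <- if ("LENGTH" %in% names(dt)) dt$LENGTH
           else if (all(c("START", "STOP") %in% names(dt)))
               dt$STOP - dt$START + 1
           else NULL
    B <- NULL
    if (!is.null(len)) {
        B <- cbind(LENGTH = len, LOG_LENGTH = log(len))
        rownames(B) <- genes
    }
    C <- NULL
    if (!is.null(geneCorrFile)) {
        cm <- fread(geneCorrFile, header = TRUE)
        C <- as.matrix(cm, rownames = 1)
        C <- C[genes, genes]
    }
    GeneStats(setNames(z, genes), confounders = B, geneCorr = C,
              traitId = traitId)
}

#' Read a two-column gene mapping table
#'
#' @param file TSV with source ids in the first column and target ids in
#'   the second.
#' @param policy `"one_to_one_ortholog"` or `"symbol_alias"`.
#' @return A [GeneMapping-class].
#' @export
readGeneMapping <- function(file,
                            policy = c("one_to_one_ortholog",
                                       "symbol_alias")) {
    dt <- fread(file, header = TRUE)
    GeneMapping(as.character(dt[[1]]), as.character(dt[[2]]),
                policy = match.arg(policy))
}

#' Write a gene set in two-column set / gene format
#'
#' @param genes character vector of gene ids.
#' @param setName name of the set (first column value).
#' @param file output TSV path.
#' @param append append to an existing file (default FALSE).
#' @export
writeGeneSet <- function(genes, setName, file, append = FALSE) {
    fwrite(data.table::data.table(set = setName, gene = genes), file,
           sep = "\t", append = append, col.names = !append)
    invisible(file)
}

#' Write workflow result tables
#'
#' Writes `step1.tsv`, `step2_pairs.tsv`, `step3_pairs.tsv`,
#' `step3_clusters.tsv` and `summary.tsv` (per-trait counts) under
#' `dir`, plus the asymmetric cross-dataset PS grid `cd_ps_matrix.tsv`
#' (rows condition columns) when step 3 produced pairs.
#'
#' @param ws a [WorkflowSummary-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeWorkflow <- function(ws, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(df, f) fwrite(df, file.path(dir, f), sep = "\t")
    out(ws@step1, "step1.tsv")
    out(ws@step2Pairs, "step2_pairs.tsv")
    out(ws@step3Pairs, "step3_pairs.tsv")
    out(ws@step3Clusters, "step3_clusters.tsv")
    out(data.frame(trait = ws@traitId, threshold = ws@threshold,
                   t(ws@counts)), "summary.tsv")
    grid <- cdPSMatrix(ws)
    if (!is.null(grid))
        fwrite(data.table::as.data.table(grid, keep.rownames = "entity"),
               file.path(dir, "cd_ps_matrix.tsv"), sep = "\t")
    invisible(dir)
}

#' Asymmetric cross-dataset PS grid
#'
#' Entry (i, j) is the proportional significance of entity j when
#' conditioning on entity i (NA on the diagonal and for colinear pairs),
#' the layout used for step-3 heatmaps.
#'
#' @param ws a [WorkflowSummary-class].
#' @return matrix or NULL when step 3 has no pairs.
#' @export
cdPSMatrix <- function(ws) {
    pr <- ws@step3Pairs
    if (is.null(pr) || !nrow(pr)) return(NULL)
    ents <- unique(c(paste(pr$dataset_a, pr$ct_a, sep = ":"),
                     paste(pr$dataset_b, pr$ct_b, sep = ":")))
    g <- matrix(NA_real_, length(ents), length(ents),
                dimnames = list(ents, ents))
    for (r in seq_len(nrow(pr))) {
        a <- paste(pr$dataset_a[r], pr$ct_a[r], sep = ":")
        b <- paste(pr$dataset_b[r], pr$ct_b[r], sep = ":")
        g[a, b] <- pr$cd_ps_b[r]  # row a conditions column b
        g[b, a] <- pr$cd_ps_a[r]
    }
    g
}
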