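#' Assemble a raw single-cell expression matrix
#'
#' Wraps a genes x cells matrix plus a cell-to-cell-type label table into a
#' \linkS4class{SingleCellExperiment} (assay `"values"`, `colData$cell_type`,
#' `metadata$unit`), the container consumed by [toCPM()] and
#' [buildProfile()]. Cells without a label are dropped with a message.
#'
#' @param values genes x cells non-negative numeric matrix with gene
#'   rownames and cell colnames.
#' @param labels either a named character vector (names = cell ids) or a
#'   two-column data.frame (cell id, cell type).
#' @param unit expression unit: `"count"`, `"UMI"`, `"CPM"`, `"RPKM"` or
#'   `"TPM"`. Counts must be converted with [toCPM()] before profiling;
#'   the other units are used as is.
#' @return A `SingleCellExperiment`.
#' @examples
#' m <- matrix(rpois(20, 5), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' sce <- rawExpression(m, setNames(rep(c("A", "B"), c(2, 3)), colnames(m)),
#'                      unit = "count")
#' @export
rawExpression <- function(values, labels,
                          unit = c("count", "UMI", "CPM", "RPKM", "TPM")) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have gene rownames and cell colnames")
    if (anyDuplicated(rownames(values)))
        stop("gene ids must be unique")
    if (any(values < 0))
        stop("expression values must be non-negative")
    if (is.data.frame(labels))
        labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
    lab <- labels[colnames(values)]
    keep <- !is.na(lab) & nzchar(lab)
    if (!any(keep))
        stop("no cell has a cell-type label")
    if (any(!keep))
        message(sum(!keep), " unlabeled cell(s) dropped")
    sce <- SingleCellExperiment(
        assays = list(values = values[, keep, drop = FALSE]),
        colData = DataFrame(cell_type = unname(lab[keep]),
                            row.names = colnames(values)[keep]))
    metadata(sce)$unit <- unit
    sce
}

#' Convert read counts to counts per million
#'
#' Rescales every cell so its values sum to 1e6, correcting for per-cell
#' sequencing depth. Only raw read counts need this step; UMI counts,
#' RPKM and TPM are used as is.
#'
#' @param sce a `SingleCellExperiment` from [rawExpression()] with unit
#'   `"count"` or `"UMI"`.
#' @return The same object with CPM values and unit `"CPM"`.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 9), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' sce <- rawExpression(m, setNames(c("A", "A"), c("c1", "c2")), "count")
#' colSums(SummarizedExperiment::assay(toCPM(sce)))
#' @export
toCPM <- function(sce) {
    unit <- metadata(sce)$unit
    if (!unit %in% c("count", "UMI"))
        stop("toCPM() expects unit 'count' or 'UMI', got '", unit, "'")
    v <- assay(sce, "values")
    tot <- colSums(v)
    if (any(tot <= 0))
        stop("cell(s) with zero total count: ",
             paste(colnames(v)[tot <= 0], collapse = ", "))
    assay(sce, "values") <- sweep(v, 2, tot / 1e6, "/")
    metadata(sce)$unit <- "CPM"
    sce
}

#' Log2-transform expression with pseudo-count 1
#'
#' @param values non-negative numeric matrix or vector.
#' @return `log2(values + 1)`, same shape.
#' @export
logTransform <- function(values) {
    if (any(values < 0))
        stop("logTransform() requires non-negative values")
    log2(values + 1)
}

#' Build a per-cell-type profile from a raw single-cell matrix
#'
#' For every cell type, averages `log2(e + 1)` over its cells (log first,
#' then average), and appends the per-gene arithmetic mean over cell types
#' as the dataset average -- the conditioning covariate of the
#' gene-property regression.
#'
#' @param sce a `SingleCellExperiment` from [rawExpression()] (CPM, UMI,
#'   RPKM or TPM values; convert counts with [toCPM()] first).
#' @param datasetId dataset identifier recorded in the profile.
#' @param species `"human"`, `"mouse"` or `"other"`.
#' @param minCells minimum number of cells a cell type needs to be
#'   retained (default 1).
#' @return A [CellTypeProfile-class].
#' @examples
#' m <- matrix(c(1, 3, 3, 1), 1, 4,
#'             dimnames = list("g1", paste0("c", 1:4)))
#' sce <- rawExpression(m, setNames(rep(c("A", "B"), 2),
#'                      paste0("c", 1:4)), "CPM")
#' exprValues(buildProfile(sce))
#' @export
buildProfile <- function(sce, datasetId = "dataset",
                         species = c("other", "human", "mouse"),
                         minCells = 1L) {
    species <- match.arg(species)
    if (identical(metadata(sce)$unit, "count"))
        warning("profiling raw counts; convert with toCPM() first ",
                "unless this is intended")
    lab <- sce$cell_type
    if (is.null(lab) || !length(lab))
        stop("no labeled cells available")
    counts <- table(lab)
    keep <- names(counts)[counts >= minCells]
    if (!length(keep))
        stop("no cell type has at least ", minCells, " cells")
    lv <- logTransform(assay(sce, "values")[, lab %in% keep, drop = FALSE])
    lab <- lab[lab %in% keep]
    grp <- sort(unique(lab))
    E <- t(rowsum(t(lv), lab)[grp, , drop = FALSE] / as.vector(table(lab)[grp]))
    CellTypeProfile(E, datasetId = datasetId, species = species)
}

#' Restrict a profile to a subset of cell types
#'
#' Drops all other cell-type columns and recomputes the average over the
#' retained ones. Because the average defines specificity, the subsetted
#' profile tests expression relative to the retained cell types only
#' (e.g. conditioning a brain cell type on the brain-wide rather than the
#' body-wide average).
#'
#' @param profile a [CellTypeProfile-class].
#' @param keep character vector of cell-type names to retain (non-empty).
#' @return A [CellTypeProfile-class] over `keep` with recomputed average.
#' @export
subsetProfile <- function(profile, keep) {
    if (!length(keep))
        stop("'keep' must name at least one cell type")
    missing <- setdiff(keep, cellTypes(profile))
    if (length(missing))
        stop("unknown cell type(s): ", paste(missing, collapse = ", "))
    profile[, keep]
}

#' Map profile gene identifiers to a target namespace
#'
#' Renames genes according to a [GeneMapping-class] (e.g. mouse-to-human
#' one-to-one orthologs, or symbol/alias resolution). Unmapped genes are
#' dropped; when two source genes map to the same target id, both are
#' dropped (duplicated target ids are excluded).
#'
#' @param profile a [CellTypeProfile-class] with genes in the mapping's
#'   source namespace.
#' @param mapping a [GeneMapping-class].
#' @return The profile with target gene ids; a message reports the
#'   surviving row count.
#' @export
mapGenes <- function(profile, mapping) {
    src <- rownames(profile)
    idx <- match(src, mapping@source)
    tgt <- mapping@target[idx]
    mapped <- !is.na(tgt)
    if (!any(mapped))
        stop("no profile gene is present in the mapping")
    dupTargets <- unique(tgt[mapped][duplicated(tgt[mapped])])
    keep <- mapped & !tgt %in% dupTargets
    if (!any(keep))
        stop("no profile gene survives duplicate-target exclusion")
    out <- profile[keep, ]
    rownames(out) <- tgt[keep]
    message(sum(keep), " of ", length(src),
            " genes mapped (", sum(mapped) - sum(keep),
            " dropped as duplicated target ids)")
    validObject(out)
    out
}

#' Build a tissue profile from a TPM matrix
#'
#' GTEx-style construction: keep genes whose per-tissue average TPM
#' exceeds 1 in at least one tissue, winsorize values at 50 (values above
#' 50 are set to 50), log2-transform with pseudo-count 1, and append the
#' across-tissue average.
#'
#' @param tpm genes x tissues non-negative matrix of per-tissue average
#'   TPM with dimnames.
#' @param datasetId dataset identifier (default `"tissue"`).
#' @param winsorAt winsorization cap before the log transform (default 50).
#' @param minTPM inclusion threshold (default 1; strict `>`).
#' @return A [CellTypeProfile-class] over tissues.
#' @export
tissueProfile <- function(tpm, datasetId = "tissue", winsorAt = 50,
                          minTPM = 1) {
    tpm <- as.matrix(tpm)
    if (any(tpm < 0))
        stop("TPM values must be non-negative")
    keep <- apply(tpm, 1, max) > minTPM
    if (!any(keep))
        stop("no gene exceeds TPM ", minTPM, " in any tissue")
    x <- pmin(tpm[keep, , drop = FALSE], winsorAt)
    CellTypeProfile(logTransform(x), datasetId = datasetId,
                    species = "human")
}
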