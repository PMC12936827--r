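#' @importFrom utils read.delim read.csv write.table
NULL

# header aliases, matched case-insensitively after stripping "._ " characters
.NPX_ALIASES <- list(
    sample_id = c("sampleid", "sample", "samplename"),
    assay_id = c("assayid", "assay", "olinkid", "protein", "proteinid"),
    npx = c("npx", "npxvalue", "value"),
    gene_symbol = c("genesymbol", "gene", "genename", "symbol"),
    uniprot_id = c("uniprotid", "uniprot"),
    panel_name = c("panelname", "panel"),
    lod = c("lod", "limitofdetection"),
    qc_warning = c("qcwarning", "qcwarn", "qcflag"),
    subject_id = c("subjectid", "subject", "patientid", "patient"),
    arm = c("arm", "group", "treatmentgroup", "allocation"),
    timepoint = c("timepoint", "time", "visit"),
    sex = c("sex", "gender"),
    age = c("age"),
    nihss = c("nihss", "nihssscore"),
    esrs = c("esrs", "esrsscore")
)

.ARM_SPELLINGS <- list(
    treatment = c("treatment", "treat", "t", "ipc", "intervention", "active"),
    control = c("control", "ctrl", "c", "placebo")
)

.TIMEPOINT_SPELLINGS <- list(
    baseline = c("baseline", "pre", "t1", "c1", "1", "v1", "day0"),
    post = c("post", "postintervention", "t2", "c2", "2", "v2", "followup")
)

.normKey <- function(x) gsub("[._ -]", "", tolower(x))

.canonicalNames <- function(nms) {
    key <- .normKey(nms)
    out <- nms
    for (canon in names(.NPX_ALIASES)) {
        hit <- key %in% c(.normKey(canon), .NPX_ALIASES[[canon]])
        out[hit] <- canon
    }
    out
}

.mapLevels <- function(x, spellings, what) {
    key <- .normKey(as.character(x))
    out <- rep(NA_character_, length(key))
    for (canon in names(spellings))
        out[key %in% c(canon, spellings[[canon]])] <- canon
    bad <- is.na(out) & !is.na(x) & nzchar(key)
    if (any(bad)) {
        accepted <- paste(vapply(names(spellings), function(canon)
            sprintf("%s (%s)", canon,
                    paste(spellings[[canon]], collapse = ", ")),
            character(1)), collapse = "; ")
        stop(sprintf("unparseable %s label(s): %s; accepted spellings: %s",
                     what, paste(unique(x[bad]), collapse = ", "), accepted))
    }
    out
}

# sep auto-detection: a tab in the header line wins over commas
.readTable <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header))
        read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    else
        read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read NPX long-format and sample-annotation files
#'
#' Builds an [NPXExperiment-class] from a long-format NPX table (one row per
#' sample x assay, columns at least `sample_id`, `assay_id`, `npx`) and a
#' sample-annotation table (at least `sample_id`, `subject_id`, `arm`,
#' `timepoint`; optionally `sex`, `age`, `nihss`, `esrs`). Tab- or
#' comma-separated dialect is auto-detected from the header line; header
#' names are matched case-insensitively against an alias table (e.g.
#' `Assay`/`OlinkID` for the assay id, `NPX` for the value). The matrix
#' covers the Cartesian product of observed assays and annotated samples;
#' cells with no row in the file, or with NPX recorded as `NA`/`NaN`/empty,
#' are missing (`NA`). Arm labels accepted include treatment/treat/IPC vs
#' control/ctrl; timepoint labels baseline/pre/T1/1 vs post/T2/2.
#'
#' No imputation is performed here or anywhere downstream: contrasts use
#' per-protein complete observations (complete pairs for paired contrasts).
#' LOD / QC-warning columns, when present, are carried through as per-cell
#' annotations but do not filter data.
#'
#' @param npxPath path to the NPX long-format CSV/TSV.
#' @param annotationPath path to the sample annotation CSV/TSV.
#' @return an [NPXExperiment-class].
#' @export
readNpxLong <- function(npxPath, annotationPath) {
    if (!file.exists(npxPath)) stop("NPX file not found: ", npxPath)
    if (!file.exists(annotationPath))
        stop("annotation file not found: ", annotationPath)
    npx <- .readTable(npxPath)
    names(npx) <- .canonicalNames(names(npx))
    ann <- .readTable(annotationPath)
    names(ann) <- .canonicalNames(names(ann))

    need <- c("sample_id", "assay_id", "npx")
    if (!all(need %in% names(npx)))
        stop("NPX file must have columns (after alias matching): ",
             paste(setdiff(need, names(npx)), collapse = ", "))
    need_ann <- c("sample_id", "subject_id", "arm", "timepoint")
    if (!all(need_ann %in% names(ann)))
        stop("annotation file must have columns (after alias matching): ",
             paste(setdiff(need_ann, names(ann)), collapse = ", "))

    npx$sample_id <- as.character(npx$sample_id)
    npx$assay_id <- as.character(npx$assay_id)
    key <- paste(npx$sample_id, npx$assay_id, sep = "\r")
    if (anyDuplicated(key)) {
        d <- npx[duplicated(key), c("sample_id", "assay_id"), drop = FALSE][1, ]
        stop(sprintf("duplicate (sample_id, assay_id) rows, e.g. (%s, %s)",
                     d$sample_id, d$assay_id))
    }
    ann$sample_id <- as.character(ann$sample_id)
    orphan <- setdiff(unique(npx$sample_id), ann$sample_id)
    if (length(orphan))
        stop("sample(s) present in NPX file but absent from annotations: ",
             paste(orphan, collapse = ", "))

    ann$arm <- .mapLevels(ann$arm, .ARM_SPELLINGS, "arm")
    ann$timepoint <- .mapLevels(ann$timepoint, .TIMEPOINT_SPELLINGS,
                                "timepoint")

    assays_seen <- sort(unique(npx$assay_id))
    samples_seen <- ann$sample_id
    vals <- suppressWarnings(as.numeric(npx$npx))  # "NA"/"NaN"/"" -> NA
    m <- matrix(NA_real_, length(assays_seen), length(samples_seen),
                dimnames = list(assays_seen, samples_seen))
    m[cbind(match(npx$assay_id, assays_seen),
            match(npx$sample_id, samples_seen))] <- vals

    prot <- DataFrame(assay_id = assays_seen)
    for (col in c("gene_symbol", "uniprot_id", "panel_name")) {
        if (col %in% names(npx)) {
            first <- npx[!duplicated(npx$assay_id), , drop = FALSE]
            prot[[col]] <- as.character(
                first[[col]][match(assays_seen, first$assay_id)])
        }
    }
    x <- NPXExperiment(m, proteins = prot, samples = ann)
    for (col in c("lod", "qc_warning")) {
        if (col %in% names(npx)) {
            a <- matrix(NA, nrow(x), ncol(x), dimnames = dimnames(m))
            a[cbind(match(npx$assay_id, assays_seen),
                    match(npx$sample_id, samples_seen))] <- npx[[col]]
            assays(x, withDimnames = FALSE)[[col]] <- a
        }
    }
    validObject(x)
    x
}

#' Write an NPXExperiment back to long-format files
#'
#' Inverse of [readNpxLong()]: non-missing cells are written one row per
#' sample x assay, annotations one row per sample. Reading the files back
#' reproduces the cell set and values exactly (ordering aside).
#'
#' @param x an [NPXExperiment-class].
#' @param npxPath,annotationPath output paths; extension `.tsv` selects tabs,
#'   anything else commas.
#' @return invisibly, the two paths.
#' @export
writeNpxLong <- function(x, npxPath, annotationPath) {
    stopifnot(is(x, "NPXExperiment"))
    m <- npxValues(x)
    idx <- which(!is.na(m), arr.ind = TRUE)
    long <- data.frame(sample_id = colnames(m)[idx[, 2]],
                       assay_id = rownames(m)[idx[, 1]],
                       npx = m[idx], stringsAsFactors = FALSE)
    rd <- as.data.frame(rowData(x))
    extra <- intersect(c("gene_symbol", "uniprot_id", "panel_name"),
                       colnames(rd))
    for (col in extra)
        long[[col]] <- rd[[col]][match(long$assay_id, rd$assay_id)]
    ann <- as.data.frame(colData(x))
    sep1 <- if (grepl("\\.tsv$", npxPath)) "\t" else ","
    sep2 <- if (grepl("\\.tsv$", annotationPath)) "\t" else ","
    write.table(long, npxPath, sep = sep1, row.names = FALSE, quote = FALSE)
    write.table(ann, annotationPath, sep = sep2, row.names = FALSE,
                quote = FALSE)
    invisible(c(npxPath, annotationPath))
}

#' Derive the four-group pairing structure from sample annotations
#'
#' Partitions the samples of an [NPXExperiment-class] into the four study
#' cells (T1 = treatment baseline, T2 = treatment post, C1 = control
#' baseline, C2 = control post), identifies subjects with a complete
#' baseline/post pair per arm, and lists subjects lacking one timepoint as
#' unpaired (they are excluded from paired contrasts only). A subject
#' annotated in both arms, or an empty study cell, is an error.
#'
#' The result is a pure function of the annotation content: it does not
#' depend on sample order, and re-validating changes nothing.
#'
#' @param x an [NPXExperiment-class].
#' @return a [StudyDesign-class].
#' @export
validateDesign <- function(x) {
    stopifnot(is(x, "NPXExperiment"))
    cd <- colData(x)
    arm_by_subject <- split(as.character(cd$arm), as.character(cd$subject_id))
    both <- names(arm_by_subject)[vapply(arm_by_subject,
                                         function(a) length(unique(a)) > 1L,
                                         logical(1))]
    if (length(both))
        stop("subject(s) annotated in both arms: ",
             paste(both, collapse = ", "))
    cell <- function(arm, tp)
        sort(as.character(cd$sample_id[cd$arm == arm & cd$timepoint == tp]))
    groups <- list(T1 = cell("treatment", "baseline"),
                   T2 = cell("treatment", "post"),
                   C1 = cell("control", "baseline"),
                   C2 = cell("control", "post"))
    empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
    if (length(empty))
        stop("empty study group(s): ", paste(empty, collapse = ", "))
    paired <- lapply(c(treatment = "treatment", control = "control"),
                     function(arm) {
        sub <- cd[cd$arm == arm, , drop = FALSE]
        tps <- split(as.character(sub$timepoint), as.character(sub$subject_id))
        sort(names(tps)[vapply(tps, function(tp)
            all(TIMEPOINT_LEVELS %in% tp), logical(1))])
    })
    unpaired <- sort(setdiff(unique(as.character(cd$subject_id)),
                             unlist(paired, use.names = FALSE)))
    new("StudyDesign", groups = groups, pairedSubjects = paired,
        unpairedSubjects = unpaired)
}
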