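#' Accessors for NPXExperiment, StudyDesign, ScreenSets and SimulationTruth
#'
#' `npxValues` returns the proteins x samples NPX matrix (`NA` = missing);
#' `npxMissing` the logical missing mask; `proteinInfo` / `sampleInfo` the
#' row and column annotation as DataFrames; `assayIds` the protein ids.
#' `designGroups` returns the named list of T1/T2/C1/C2 sample ids,
#' `pairedSubjects` the per-arm paired subject lists, `unpairedSubjects`
#' those excluded from paired contrasts. `screenSet` extracts one of the
#' screening sets (`"set1"` .. `"set5"`, `"core"`) and `screenUniverse` the
#' screened protein universe. `truthTable` returns the per-protein ground
#' truth of a simulation.
#'
#' @param x the object.
#' @param which for `screenSet`, which set to extract.
#' @name accessors
NULL

#' @rdname accessors
#' @export
npxValues <- function(x) {
    stopifnot(is(x, "NPXExperiment"))
    assay(x, "npx")
}

#' @rdname accessors
#' @export
npxMissing <- function(x) is.na(npxValues(x))

#' @rdname accessors
#' @export
proteinInfo <- function(x) rowData(x)

#' @rdname accessors
#' @export
sampleInfo <- function(x) colData(x)

#' @rdname accessors
#' @export
assayIds <- function(x) as.character(rowData(x)$assay_id)

#' @rdname accessors
#' @export
designGroups <- function(x) {
    stopifnot(is(x, "StudyDesign"))
    x@groups
}

#' @rdname accessors
#' @export
pairedSubjects <- function(x) {
    stopifnot(is(x, "StudyDesign"))
    x@pairedSubjects
}

#' @rdname accessors
#' @export
unpairedSubjects <- function(x) {
    stopifnot(is(x, "StudyDesign"))
    x@unpairedSubjects
}

#' @rdname accessors
#' @export
screenSet <- function(x, which = c("core", "set1", "set2", "set3", "set4",
                                   "set5")) {
    stopifnot(is(x, "ScreenSets"))
    which <- match.arg(which)
    slot(x, which)
}

#' @rdname accessors
#' @export
screenUniverse <- function(x) {
    stopifnot(is(x, "ScreenSets"))
    x@universe
}

#' @rdname accessors
#' @export
truthTable <- function(x) {
    stopifnot(is(x, "SimulationTruth"))
    x@proteins
}

setMethod("show", "NPXExperiment", function(object) {
    cat("NPXExperiment:", nrow(object), "proteins x", ncol(object),
        "samples\n")
    cd <- colData(object)
    tab <- table(arm = cd$arm, timepoint = cd$timepoint)
    cat("  samples per cell:\n")
    print(tab)
    nm <- sum(is.na(assay(object, "npx")))
    cat("  missing NPX cells:", nm, "\n")
    invisible(NULL)
})

setMethod("show", "StudyDesign", function(object) {
    n <- vapply(object@groups, length, integer(1))
    cat("StudyDesign: T1 =", n[["T1"]], " T2 =", n[["T2"]],
        " C1 =", n[["C1"]], " C2 =", n[["C2"]], "\n")
    cat("  paired subjects: treatment =",
        length(object@pairedSubjects$treatment), ", control =",
        length(object@pairedSubjects$control), "\n")
    if (length(object@unpairedSubjects))
        cat("  unpaired subjects:",
            paste(object@unpairedSubjects, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "ScreenSets", function(object) {
    cat("ScreenSets (alpha =", object@alpha, ", rule =",
        object@membershipRule, ")\n")
    for (s in c("set1", "set2", "set3", "set4", "set5", "core"))
        cat(sprintf("  %-5s n = %d\n", s, length(slot(object, s))))
    cat("  universe:", length(object@universe), "proteins\n")
    invisible(NULL)
})

setMethod("show", "SimulationTruth", function(object) {
    cat("SimulationTruth:", nrow(object@proteins), "proteins, seed =",
        object@seed, "\n")
    print(table(object@proteins$class))
    invisible(NULL)
})
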