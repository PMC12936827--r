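#' @importFrom stats phyper
NULL

#' Read a GMT term-set collection
#'
#' Parses the standard tab-separated GMT format: one term per line,
#' `term_id <TAB> description <TAB> member1 <TAB> member2 ...`. Members are
#' uppercased for matching; duplicate members within a term are deduplicated
#' with a message. A line with fewer than three fields, or a duplicated
#' term id, is an error naming the line.
#'
#' @param path path to a GMT file.
#' @return named list of terms; each element is a character vector of
#'   members with attribute `description`.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has %d field(s); need term, %s",
                         i, length(f), "description and >= 1 member"))
        id <- f[[1]]
        if (id %in% names(out))
            stop(sprintf("duplicate term_id '%s' at GMT line %d", id, i))
        members <- toupper(f[-(1:2)])
        members <- members[nzchar(members)]
        if (anyDuplicated(members)) {
            message(sprintf("term '%s': %d duplicate member(s) removed",
                            id, sum(duplicated(members))))
            members <- unique(members)
        }
        attr(members, "description") <- f[[2]]
        out[[id]] <- members
    }
    out
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term for over-representation of the query set against a
#' background universe. With N annotated background proteins, K of them in
#' the term, and n annotated query proteins of which k fall in the term, the
#' p-value is the upper tail P(X >= k) for X ~ Hypergeometric(N, K, n).
#' By default the urn is annotation-restricted: the background (and hence
#' the query) is intersected with the union of all term members, keeping N
#' interpretable; set `restrictToAnnotated = FALSE` to count the full
#' background. Terms with no annotated background member are skipped.
#' q is Benjamini-Hochberg across the tested terms.
#'
#' @param query character vector of gene symbols (the candidate set).
#' @param background character vector of gene symbols; must contain the
#'   query.
#' @param terms a collection from [readGmt()].
#' @param alpha threshold for the `significant` flag (raw p; q reported
#'   alongside).
#' @param restrictToAnnotated restrict the urn to annotated proteins
#'   (default TRUE).
#' @return data.frame with `term_id`, `description`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`, ordered by p.
#' @export
hypergeomOra <- function(query, background, terms, alpha = 0.05,
                         restrictToAnnotated = TRUE) {
    query <- toupper(query)
    background <- unique(toupper(background))
    outside <- setdiff(query, background)
    if (length(outside))
        stop("query protein(s) outside background: ",
             paste(outside, collapse = ", "))
    annotated <- unique(unlist(terms, use.names = FALSE))
    if (restrictToAnnotated) {
        background <- intersect(background, annotated)
        query <- intersect(query, background)
    }
    N <- length(background)
    n <- length(unique(query))
    rows <- lapply(names(terms), function(id) {
        members <- intersect(terms[[id]], background)
        K <- length(members)
        if (K == 0L) return(NULL)
        k <- length(intersect(unique(query), members))
        data.frame(term_id = id,
                   description = attr(terms[[id]], "description"),
                   k = k, K = K, n = n, N = N,
                   p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term_id = character(), description = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), q = numeric(),
                          significant = logical()))
    out$q <- bhFdr(out$p)
    out$significant <- out$p < alpha
    out[order(out$p), , drop = FALSE]
}

#' Venn partition of significant terms across enrichment results
#'
#' Given enrichment tables for two or more query sets, partitions the union
#' of significant term ids (raw p < alpha) into the regions of the Venn
#' diagram. The region shared by all tables is reported first.
#'
#' @param results named list of [hypergeomOra()] tables (>= 2).
#' @param alpha significance threshold for region membership.
#' @return data.frame with `region` (e.g. `"set3&set5"`), `n_terms`, and
#'   `term_ids` (comma-separated); the all-shared region first, then by
#'   decreasing region order.
#' @export
intersectEnrichments <- function(results, alpha = 0.05) {
    if (length(results) < 2L)
        stop("need at least 2 enrichment tables")
    if (is.null(names(results)) || any(!nzchar(names(results))))
        names(results) <- paste0("set", seq_along(results))
    sig <- lapply(results, function(r) r$term_id[r$p < alpha])
    universe <- unique(unlist(sig, use.names = FALSE))
    if (!length(universe))
        return(data.frame(region = character(), n_terms = integer(),
                          term_ids = character()))
    membership <- vapply(sig, function(s) universe %in% s,
                         logical(length(universe)))
    membership <- matrix(membership, nrow = length(universe),
                         dimnames = list(universe, names(sig)))
    region <- apply(membership, 1L, function(z)
        paste(names(sig)[z], collapse = "&"))
    regions <- split(universe, region)
    ord <- order(-vapply(names(regions), function(r)
        lengths(regmatches(r, gregexpr("&", r))) + 1L, numeric(1)))
    regions <- regions[ord]
    all_name <- paste(names(sig), collapse = "&")
    if (all_name %in% names(regions))  # all-shared region first
        regions <- c(regions[all_name],
                     regions[setdiff(names(regions), all_name)])
    data.frame(region = names(regions),
               n_terms = lengths(regions),
               term_ids = vapply(regions, paste, character(1),
                                 collapse = ","),
               row.names = NULL, stringsAsFactors = FALSE)
}
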