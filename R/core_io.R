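# Data ingestion and the pre-analysis filters: reverse coding, listwise
# deletion, and sparse-category collapsing.

#' Construct a ResponseMatrix
#'
#' @param responses numeric/integer matrix or data.frame of codes in
#'   \code{1..K} (NA = missing).
#' @param K nominal number of response categories (default 4).
#' @param personIds,itemIds optional identifiers; default to existing
#'   dimnames or generated ones.
#' @return a \code{\linkS4class{ResponseMatrix}}
#' @export
responseMatrix <- function(responses, K = 4L, personIds = NULL,
                           itemIds = NULL) {
  m <- as.matrix(responses)
  storage.mode(m) <- "integer"
  if (is.null(personIds))
    personIds <- rownames(m) %||% paste0("p", seq_len(nrow(m)))
  if (is.null(itemIds))
    itemIds <- colnames(m) %||% paste0("item_", seq_len(ncol(m)))
  dimnames(m) <- list(as.character(personIds), as.character(itemIds))
  new("ResponseMatrix", responses = m, K = as.integer(K))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a ScaleDefinition
#'
#' @param subscales named list: subscale name -> ordered item-id vector.
#' @param reverseItems item ids scored in the reverse direction.
#' @export
scaleDefinition <- function(subscales, reverseItems = character(0)) {
  new("ScaleDefinition",
      subscales = lapply(subscales, as.character),
      reverseItems = as.character(reverseItems))
}

#' Read a ScaleDefinition from YAML or JSON
#'
#' The file must contain a \code{subscales} mapping (name -> item-id list)
#' and optionally a \code{reverse_items} list.
#'
#' @param path file path; format chosen by extension (.yaml/.yml/.json).
#' @export
readScaleDefinition <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported scale definition format: .", ext))
  if (is.null(raw$subscales)) stop("scale definition lacks 'subscales'")
  scaleDefinition(raw$subscales,
                  as.character(raw$reverse_items %||% character(0)))
}

#' The bundled 32-item HIV Stigma Scale definition
#'
#' Four subscales (Personalized stigma: 11 items; Disclosure concerns: 8;
#' Concerns about public attitudes: 6; Negative self-image: 7) with items
#' 8 and 21 reverse-scored. Item ids follow the instrument numbering
#' (\code{item_1} ... \code{item_39}, 32 items in total).
#'
#' @export
hivStigmaScale32 <- function() {
  readScaleDefinition(system.file("extdata", "hiv_stigma_scale_32.yaml",
                                  package = "hybridDIF", mustWork = TRUE))
}

#' Load ordinal responses from CSV
#'
#' Expects one row per respondent with one column per item id plus a group
#' column; blank cells are missing. Codes outside \code{[1, K]} or
#' non-integer cells are rejected with the offending location named.
#'
#' @param path CSV file (UTF-8, header row).
#' @param scale a \code{\linkS4class{ScaleDefinition}} naming the item
#'   columns to read.
#' @param groupColumn name of the group column.
#' @param K number of response categories (default 4).
#' @param idColumn optional person-id column; row numbers otherwise.
#' @return list with elements \code{responses}
#'   (\code{\linkS4class{ResponseMatrix}}) and \code{groups} (factor with
#'   NA for missing labels).
#' @export
loadResponses <- function(path, scale, groupColumn = "group", K = 4L,
                          idColumn = NULL) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 na.strings = c("", "NA"))
  items <- scaleItems(scale)
  missingCols <- setdiff(c(items, groupColumn), names(df))
  if (length(missingCols))
    stop("column(s) not found in ", path, ": ",
         paste(missingCols, collapse = ", "))
  ids <- if (!is.null(idColumn)) as.character(df[[idColumn]])
         else as.character(seq_len(nrow(df)))

  m <- matrix(NA_integer_, nrow(df), length(items),
              dimnames = list(ids, items))
  for (j in items) {
    cell <- df[[j]]
    num <- suppressWarnings(as.numeric(cell))
    badInt <- which(!is.na(cell) & (is.na(num) | num != round(num)))
    if (length(badInt))
      stop(sprintf("non-integer value '%s' in column '%s', row %d",
                   cell[badInt[1]], j, badInt[1]))
    badRange <- which(!is.na(num) & (num < 1 | num > K))
    if (length(badRange))
      stop(sprintf("code %s outside [1, %d] in column '%s', row %d",
                   cell[badRange[1]], K, j, badRange[1]))
    m[, j] <- as.integer(num)
  }
  groups <- factor(df[[groupColumn]])
  list(responses = responseMatrix(m, K = K), groups = groups)
}

#' Reverse-code the reverse-scored items
#'
#' Applies \code{code -> K + 1 - code} to the scale's reverse items so
#' higher codes mean more of the trait on every item. An involution:
#' applying it twice restores the input. Missing cells are untouched.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}}
#' @param scale a \code{\linkS4class{ScaleDefinition}}
#' @export
applyReverseCoding <- function(m, scale) {
  rev <- intersect(reverseItems(scale), itemIds(m))
  if (!length(rev)) return(m)
  r <- responses(m)
  r[, rev] <- m@K + 1L - r[, rev]
  responseMatrix(r, K = m@K)
}

#' Listwise-complete subset for a set of items
#'
#' Retains only persons with complete responses on \code{items} and a
#' non-missing group label, preserving order. Missing values are never
#' imputed; each analysis excludes its own incomplete respondents.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}}
#' @param groups factor of group labels aligned with the persons of
#'   \code{m} (NA allowed; such persons are dropped).
#' @param items item ids entering the analysis.
#' @return list(responses, groups) restricted to the retained persons and
#'   the requested items.
#' @export
listwiseSubset <- function(m, groups, items = itemIds(m)) {
  stopifnot(length(items) > 0)
  bad <- setdiff(items, itemIds(m))
  if (length(bad))
    stop("unknown item(s): ", paste(bad, collapse = ", "))
  if (length(groups) != nPersons(m))
    stop("groups must align with the persons of the response matrix")
  r <- responses(m)[, items, drop = FALSE]
  keep <- complete.cases(r) & !is.na(groups)
  if (!any(keep))
    stop("no persons remain after listwise deletion")
  g <- droplevels(factor(groups[keep]))
  list(responses = responseMatrix(r[keep, , drop = FALSE], K = m@K),
       groups = g)
}

#' Collapse sparse response categories
#'
#' Per item, while any group-by-category cell count falls below
#' \code{minCell}, the offending category is merged with its
#' inward-adjacent neighbour (category 1 into 2, K into K-1; below-centre
#' categories merge upward, above-centre downward), the same merge being
#' applied to all groups. Codes are relabelled contiguously from 1.
#' Offenders closest to the extremes are merged first, so the procedure
#' is deterministic.
#'
#' @param m a \code{\linkS4class{ResponseMatrix}} (listwise-complete for
#'   the analysis at hand).
#' @param groups factor aligned with the persons of \code{m}.
#' @param minCell minimum group-by-category count for keeping a category
#'   separate (default 5).
#' @return list(responses, report): the possibly collapsed matrix and a
#'   data.frame describing each merge (item, mergedFrom, mergedInto).
#' @export
collapseSparseCategories <- function(m, groups, minCell = 5L) {
  stopifnot(minCell >= 1L)
  groups <- droplevels(factor(groups))
  r <- responses(m)
  report <- list()
  for (j in itemIds(m)) {
    x <- r[, j]
    cats <- sort(unique(x[!is.na(x)]))   # current original-code blocks
    repeat {
      tab <- table(groups, factor(x, levels = cats))
      minPerCat <- apply(tab, 2, min)
      off <- which(minPerCat < minCell)
      if (!length(off)) break
      ncat <- length(cats)
      if (ncat <= 1L)
        stop(sprintf("item '%s' collapses to a single category (all %s < %d)",
                     j, "group-by-category counts", minCell))
      # offender closest to an extreme first; ties -> lower category
      pos <- off[order(pmin(off - 1L, ncat - off), off)][1]
      into <- if (pos <= ncat / 2) pos + 1L else pos - 1L
      report[[length(report) + 1L]] <- data.frame(
        item = j, mergedFrom = cats[pos], mergedInto = cats[into],
        stringsAsFactors = FALSE)
      x[x == cats[pos]] <- cats[into]
      cats <- cats[-pos]
      if (length(cats) == 1L)
        stop(sprintf("item '%s' collapsed to a single category", j))
    }
    # relabel contiguously 1..K'
    r[, j] <- match(x, cats)
  }
  rep_df <- if (length(report)) do.call(rbind, report)
            else data.frame(item = character(0), mergedFrom = integer(0),
                            mergedInto = integer(0))
  list(responses = responseMatrix(r, K = m@K), report = rep_df)
}
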