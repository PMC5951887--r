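# Multi-cohort synthetic Likert data with the statistical structure the
# DIF analysis assumes: group-specific trait distributions, graded
# response items, optional injected uniform/non-uniform DIF, MCAR
# missingness, and a gender covariate. The defaults mirror a three-cohort
# HIV-stigma study design (cohort sizes 250/188/598, four subscales of
# 11/8/6/7 four-category items, reverse-scored items 8 and 21).

#' Specification of a synthetic multi-cohort study
#'
#' @param groups data.frame with columns \code{name}, \code{n},
#'   \code{theta_mean}, \code{theta_sd}, \code{female} (proportion).
#'   Default: IN (n=250, mean 0.25), SE (n=188, mean -0.25), US (n=598,
#'   mean 0), SDs 1, female proportions 0.50/0.43/0.34.
#' @param scale a \code{\linkS4class{ScaleDefinition}}; default the
#'   bundled 32-item HIV Stigma Scale layout.
#' @param K response categories per item (default 4).
#' @param aRange discrimination prior, uniform (default c(1.2, 2.5)).
#' @param thresholdSd thresholds are sorted N(0, thresholdSd) draws.
#' @param minGap minimum threshold gap (redrawn otherwise, default 0.3);
#'   keeps all categories populated at study-size samples.
#' @param difInjections data.frame with columns \code{item},
#'   \code{group}, \code{kind} ("uniform" adds \code{magnitude} to every
#'   threshold of the item for that group; "nonuniform" multiplies the
#'   discrimination by \code{magnitude}, which must be > 0) and
#'   \code{magnitude}. Default: none.
#' @param missingRate MCAR cell-missingness probability (default 0.02).
#' @param nGenderMissing number of persons with a missing gender label
#'   (default 1, emulating a recoded third-category respondent).
#' @param seed integer seed.
#' @return list of class \code{StudySpec}
#' @export
studySpec <- function(groups = NULL, scale = NULL, K = 4L,
                      aRange = c(1.2, 2.5), thresholdSd = 1, minGap = 0.3,
                      difInjections = NULL, missingRate = 0.02,
                      nGenderMissing = 1L, seed = NULL) {
  groups <- groups %||% data.frame(
    name = c("IN", "SE", "US"), n = c(250L, 188L, 598L),
    theta_mean = c(0.25, -0.25, 0), theta_sd = 1,
    female = c(0.50, 0.43, 0.34), stringsAsFactors = FALSE)
  scale <- scale %||% hivStigmaScale32()
  difInjections <- difInjections %||% data.frame(
    item = character(0), group = character(0), kind = character(0),
    magnitude = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(groups$n >= 1L), all(is.finite(difInjections$magnitude)),
            K >= 2L, missingRate >= 0, missingRate < 1)
  if (any(difInjections$kind == "nonuniform" & difInjections$magnitude <= 0))
    stop("non-uniform DIF magnitude must be > 0 (discrimination multiplier)")
  if (!all(difInjections$item %in% scaleItems(scale)))
    stop("DIF injection names an unknown item")
  if (!all(difInjections$group %in% groups$name))
    stop("DIF injection names an unknown group")
  structure(list(groups = groups, scale = scale, K = as.integer(K),
                 aRange = aRange, thresholdSd = thresholdSd,
                 minGap = minGap, difInjections = difInjections,
                 missingRate = missingRate,
                 nGenderMissing = as.integer(nGenderMissing), seed = seed),
            class = "StudySpec")
}

drawItemParams <- function(spec, items) {
  a <- setNames(runif(length(items), spec$aRange[1], spec$aRange[2]), items)
  b <- setNames(vector("list", length(items)), items)
  for (j in items) {
    repeat {
      cand <- sort(rnorm(spec$K - 1L, 0, spec$thresholdSd))
      if (all(diff(cand) >= spec$minGap)) { b[[j]] <- cand; break }
    }
  }
  list(a = a, b = b)
}

#' Generate a synthetic multi-cohort study
#'
#' Draws group trait values, item parameters from the priors, applies
#' any DIF injections to the affected group's response-generating
#' parameters (all other groups share the base item), samples responses
#' from the graded response model, applies MCAR missingness, and flips
#' the scale's reverse-scored items onto the instrument scale (so the
#' written data need \code{\link{applyReverseCoding}} before analysis,
#' as real data would). Fully reproducible under the spec's seed.
#'
#' @param spec a \code{\link{studySpec}}
#' @return list: \code{responses} (\code{\linkS4class{ResponseMatrix}},
#'   instrument-coded), \code{groups} (factor), \code{gender} (factor
#'   with possible NA), \code{theta} (true traits), \code{truth} (item
#'   parameters per group, injections, spec).
#' @export
generateStudy <- function(spec = studySpec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  items <- scaleItems(spec$scale)
  base <- drawItemParams(spec, items)

  nTotal <- sum(spec$groups$n)
  groups <- factor(rep(spec$groups$name, spec$groups$n),
                   levels = spec$groups$name)
  theta <- unlist(Map(function(n, mu, sd) rnorm(n, mu, sd),
                      spec$groups$n, spec$groups$theta_mean,
                      spec$groups$theta_sd), use.names = FALSE)
  ids <- paste0("p", seq_len(nTotal))

  # per-group generating parameters (base + injections)
  paramsFor <- function(g) {
    a <- base$a; b <- base$b
    inj <- spec$difInjections[spec$difInjections$group == g, , drop = FALSE]
    for (i in seq_len(nrow(inj))) {
      j <- inj$item[i]
      if (inj$kind[i] == "uniform") b[[j]] <- b[[j]] + inj$magnitude[i]
      else if (inj$kind[i] == "nonuniform") a[[j]] <- a[[j]] * inj$magnitude[i]
      else stop("unknown DIF kind: ", inj$kind[i])
    }
    list(a = a, b = b)
  }

  resp <- matrix(NA_integer_, nTotal, length(items),
                 dimnames = list(ids, items))
  for (g in spec$groups$name) {
    rows <- which(groups == g)
    sim <- simulateGRM(paramsFor(g), theta[rows])
    resp[rows, ] <- responses(sim)
  }

  if (spec$missingRate > 0) {
    drop <- matrix(runif(length(resp)) < spec$missingRate,
                   nrow(resp), ncol(resp))
    resp[drop] <- NA_integer_
  }

  # instrument coding: reverse-scored items are stored flipped
  rev <- reverseItems(spec$scale)
  if (length(rev)) resp[, rev] <- spec$K + 1L - resp[, rev]

  female <- unlist(Map(function(n, pf) rbinom(n, 1L, pf),
                       spec$groups$n, spec$groups$female), use.names = FALSE)
  gender <- factor(ifelse(female == 1L, "female", "male"),
                   levels = c("female", "male"))
  if (spec$nGenderMissing > 0L)
    gender[sample(nTotal, min(spec$nGenderMissing, nTotal))] <- NA

  list(responses = responseMatrix(resp, K = spec$K),
       groups = groups, gender = gender, theta = theta,
       truth = list(itemParams = base,
                    groupParams = setNames(
                      lapply(spec$groups$name, paramsFor),
                      spec$groups$name),
                    injections = spec$difInjections,
                    spec = spec[setdiff(names(spec), "scale")]))
}

#' Write a generated study to disk
#'
#' Produces \code{responses.csv} (person_id, group, gender, one column
#' per item), \code{scale.yaml} and \code{truth.json}; the CSV
#' round-trips through \code{\link{loadResponses}}.
#'
#' @param study result of \code{\link{generateStudy}}
#' @param dir output directory (created if needed)
#' @param scale the \code{\linkS4class{ScaleDefinition}} used (default
#'   the bundled 32-item layout)
#' @return named character vector of the files written
#' @export
writeStudy <- function(study, dir, scale = hivStigmaScale32()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- responses(study$responses)
  df <- data.frame(person_id = rownames(r),
                   group = as.character(study$groups),
                   gender = as.character(study$gender),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(r, check.names = FALSE))
  csv <- file.path(dir, "responses.csv")
  write.csv(df, csv, row.names = FALSE, quote = FALSE, na = "")

  yml <- file.path(dir, "scale.yaml")
  yaml::write_yaml(list(subscales = subscales(scale),
                        reverse_items = as.list(reverseItems(scale))), yml)

  truth <- file.path(dir, "truth.json")
  tr <- study$truth
  jsonlite::write_json(
    list(itemParams = list(a = as.list(tr$itemParams$a),
                           b = tr$itemParams$b),
         injections = tr$injections,
         injectedItems = unique(tr$injections$item),
         spec = tr$spec[c("K", "aRange", "thresholdSd", "minGap",
                          "missingRate")],
         groups = tr$spec$groups),
    truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  c(responses = csv, scale = yml, truth = truth)
}
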