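NATURE_SCORES <- c("cold" = -3, "mild cold" = -2, "cool" = -1, "neutral" = 0,
                   "mild warm" = 1, "warm" = 2, "hot" = 3)
FLAVOR_SCORES <- c("sweet" = 1, "mild sweet" = 0.5,
                   "pungent" = 1, "mild pungent" = 0.5,
                   "plain" = 1,
                   "sour" = -1, "mild sour" = -0.5,
                   "bitter" = -1, "mild bitter" = -0.5,
                   "salty" = -1, "mild salty" = -0.5)

#' Cold-hot nature score
#'
#' Maps the seven-grade TCM nature vocabulary onto integers: cold (-3),
#' mild cold (-2), cool (-1), neutral (0), mild warm (1), warm (2), hot (3).
#' A missing annotation yields `NA`.
#'
#' @param nature_token character vector of nature tokens (or `NA`).
#' @return numeric vector of scores in `{-3,...,3}` with `NA` propagated.
#' @examples
#' nature_score("hot")      # 3
#' nature_score("neutral")  # 0
#' @export
nature_score <- function(nature_token) {
  out <- rep(NA_real_, length(nature_token))
  known <- !is.na(nature_token)
  bad <- known & !(nature_token %in% names(NATURE_SCORES))
  if (any(bad))
    stop("unknown nature token(s): ",
         paste(unique(nature_token[bad]), collapse = ", "))
  out[known] <- unname(NATURE_SCORES[nature_token[known]])
  out
}

#' Flavor (yin-yang of taste) score
#'
#' Sums the per-token flavor values: sweet, pungent and plain are yang (+1;
#' their mild grades +0.5), sour, bitter and salty are yin (-1; mild grades
#' -0.5). A medicinal annotated sweet and mild pungent scores 1 + 0.5 = 1.5.
#' An empty token set yields `NA` (no flavor annotation).
#'
#' @param flavor_tokens character vector of flavor tokens for one medicinal,
#'   or a list of such vectors.
#' @return numeric score (or vector of scores for a list input).
#' @examples
#' flavor_score(c("sweet", "mild pungent"))  # 1.5
#' @export
flavor_score <- function(flavor_tokens) {
  if (is.list(flavor_tokens))
    return(vapply(flavor_tokens, flavor_score, 0))
  if (length(flavor_tokens) == 0L || all(is.na(flavor_tokens)))
    return(NA_real_)
  bad <- !(flavor_tokens %in% names(FLAVOR_SCORES))
  if (any(bad))
    stop("unknown flavor token(s): ",
         paste(unique(flavor_tokens[bad]), collapse = ", "))
  sum(unname(FLAVOR_SCORES[flavor_tokens]))
}

#' Yin-yang score
#'
#' The composite yin-yang score of a medicinal is the sum of its nature
#' (cold-hot) score and its flavor score. `mode` selects the components:
#' `"full"` (nature + flavor), `"flavor_only"`, or `"nature_only"`. The
#' result is `NA` whenever a required component is `NA`.
#'
#' @param nature_token nature token or `NA`.
#' @param flavor_tokens character vector of flavor tokens (possibly empty).
#' @param mode one of `"full"`, `"flavor_only"`, `"nature_only"`.
#' @return numeric score.
#' @export
yinyang_score <- function(nature_token, flavor_tokens,
                          mode = c("full", "flavor_only", "nature_only")) {
  mode <- match.arg(mode)
  switch(mode,
         full = nature_score(nature_token) + flavor_score(flavor_tokens),
         flavor_only = flavor_score(flavor_tokens),
         nature_only = nature_score(nature_token))
}

#' Score every medicinal in a catalog
#'
#' Builds the score table used by the phylogenetic and correlation
#' analyses: per medicinal the cold-hot score, the flavor score, and the
#' yin-yang score under the requested mode. Medicinals lacking the needed
#' annotation carry `NA` and are excluded listwise downstream.
#'
#' @param catalog a `tcm_catalog`.
#' @param mode yin-yang mode passed to [yinyang_score()].
#' @return data.frame with columns `medicinal_id`, `cold_hot`, `flavor`,
#'   `yinyang`.
#' @export
score_catalog <- function(catalog,
                          mode = c("full", "flavor_only", "nature_only")) {
  mode <- match.arg(mode)
  ch <- nature_score(catalog$nature)
  fl <- flavor_score(catalog$flavors)
  yy <- switch(mode, full = ch + fl, flavor_only = fl, nature_only = ch)
  data.frame(medicinal_id = catalog$medicinal_id,
             cold_hot = ch, flavor = fl, yinyang = yy,
             stringsAsFactors = FALSE)
}

#' Write a score table to TSV
#' @param scores data.frame from [score_catalog()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
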