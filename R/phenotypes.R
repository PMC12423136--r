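## Adjusted entry means across environments and Piepho-Moehring
## broad-sense heritability. The phenotypic model is
## y_ijk = mu + G_i + E_j + (GxE)_ij + e_ijk with genotype fixed and
## environment and interaction random. With single-replicate lines the
## interaction is not separable from the residual and the two are pooled
## into one term.

#' Adjusted entry means and heritability components per trait
#'
#' Fits the mixed model with genotype fixed and environment (and, when
#' any genotype has within-environment replication, the
#' genotype-by-environment interaction) random, by REML via lme4.
#' Returns generalized-least-squares genotype means, the mean variance
#' of a difference between two adjusted means (\eqn{\bar\nu}), the
#' genetic variance from a companion fit with genotype random, and the
#' broad-sense heritability
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \bar\nu/2)}.
#'
#' Traits observed in a single environment fall back to raw means with
#' \eqn{\bar\nu} from the residual variance (with a warning).
#'
#' @param records long data.frame with columns `line`, `env`, `trait`,
#'   `value` (a `rep` column is ignored; replication is inferred).
#' @return list with `means` (data.frame line, trait, mean) and `stats`
#'   (data.frame trait, sigma2G, vbar, H2).
#' @export
adjustedEntryMeans <- function(records) {
  stopifnot(all(c("line", "env", "trait", "value") %in% names(records)))
  meansL <- list(); statsL <- list()
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  for (tr in unique(records$trait)) {
    d <- records[records$trait == tr & !is.na(records$value), ]
    d$line <- factor(d$line)
    d$env <- factor(d$env)
    nEnv <- nlevels(d$env)
    if (nEnv < 2) {
      warning("trait ", tr, " observed in a single environment; ",
              "returning raw means")
      mu <- tapply(d$value, d$line, mean)
      resid <- unlist(tapply(d$value, d$line, function(v) v - mean(v)))
      s2 <- if (length(resid) > nlevels(d$line))
        sum(resid^2) / (length(resid) - nlevels(d$line)) else NA_real_
      vbar <- 2 * s2
      meansL[[tr]] <- data.frame(line = names(mu), trait = tr,
                                 mean = as.numeric(mu))
      statsL[[tr]] <- data.frame(trait = tr, sigma2G = var(as.numeric(mu)),
                                 vbar = vbar,
                                 H2 = NA_real_)
      next
    }
    withinRep <- anyDuplicated(paste(d$line, d$env)) > 0
    fixedForm <- if (withinRep)
      value ~ 0 + line + (1 | env) + (1 | line:env) else
      value ~ 0 + line + (1 | env)
    randForm <- if (withinRep)
      value ~ 1 + (1 | line) + (1 | env) + (1 | line:env) else
      value ~ 1 + (1 | line) + (1 | env)
    fitF <- suppressMessages(suppressWarnings(
      lme4::lmer(fixedForm, data = d, REML = TRUE, control = ctrl)))
    beta <- lme4::fixef(fitF)
    names(beta) <- sub("^line", "", names(beta))
    V <- as.matrix(stats::vcov(fitF))
    n <- nrow(V)
    vbar <- 2 * (n * sum(diag(V)) - sum(V)) / (n * (n - 1))
    sigma2G <- tryCatch({
      fitR <- suppressMessages(suppressWarnings(
        lme4::lmer(randForm, data = d, REML = TRUE, control = ctrl)))
      vc <- as.data.frame(lme4::VarCorr(fitR))
      vc$vcov[vc$grp == "line"]
    }, error = function(e) {
      # degenerate (e.g. noise-free) data: genotype variance from the means
      var(as.numeric(beta))
    })
    meansL[[tr]] <- data.frame(line = names(beta), trait = tr,
                               mean = as.numeric(beta))
    statsL[[tr]] <- data.frame(trait = tr, sigma2G = sigma2G, vbar = vbar,
                               H2 = heritability(sigma2G, vbar))
  }
  list(means = do.call(rbind, c(meansL, make.row.names = FALSE)),
       stats = do.call(rbind, c(statsL, make.row.names = FALSE)))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \bar\nu / 2)}, with
#' \eqn{\bar\nu} the mean variance of a difference between two adjusted
#' entry means.
#'
#' @param sigma2g genetic variance (>= 0).
#' @param vbar mean variance of a difference (>= 0).
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(sigma2g, vbar) {
  stopifnot(sigma2g >= 0, vbar >= 0)
  if (sigma2g == 0 && vbar == 0)
    stop("heritability undefined when both components are zero")
  sigma2g / (sigma2g + vbar / 2)
}

#' Entry means as a lines x traits matrix
#'
#' @param em result of [adjustedEntryMeans()].
#' @return numeric matrix, rownames = line ids.
#' @export
entryMeansMatrix <- function(em) {
  m <- em$means
  lines <- sort(unique(m$line))
  traits <- unique(m$trait)
  out <- matrix(NA_real_, length(lines), length(traits),
                dimnames = list(lines, traits))
  out[cbind(match(m$line, lines), match(m$trait, traits))] <- m$mean
  out
}
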