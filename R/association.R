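#' Assemble the voxel-wise regression design
#'
#' Builds the additive allele-dose model design: an intercept, the raw
#' 0/1/2 dose, age centered at the sample mean, and sex, plus the
#' requested adjustment covariates. Subjects missing any required
#' covariate are dropped (complete-case) and their ids recorded.
#'
#' @param records data.frame of subject covariates (columns subject_id,
#'   dose, age, sex, and as needed hcy, folate, apoe4).
#' @param model one of \code{"base"}, \code{"+apoe4"}, \code{"+hcy"},
#'   \code{"+folate"}, \code{"+apoe4_interaction"}.
#' @param apoe4Carrier code ApoE4 as a carrier indicator instead of
#'   allele count.
#' @return a \linkS4class{DesignMatrix}.
#' @export
assembleDesign <- function(records, model = "base", apoe4Carrier = FALSE) {
  if (nrow(records) == 0L) stop("records must be nonempty")
  model <- match.arg(model, c("base", "+apoe4", "+hcy", "+folate",
                              "+apoe4_interaction"))
  extras <- switch(model,
                   base = character(0),
                   `+apoe4` = "apoe4",
                   `+hcy` = "hcy",
                   `+folate` = "folate",
                   `+apoe4_interaction` = "apoe4")
  need <- c("dose", "age", "sex", extras)
  keep <- complete.cases(records[, need, drop = FALSE])
  dropped <- as.character(records$subject_id[!keep])
  if (length(dropped))
    message("assembleDesign: dropped ", length(dropped),
            " incomplete subjects: ", paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  r <- records[keep, , drop = FALSE]
  apoe <- if (apoe4Carrier) as.integer(r$apoe4 > 0) else r$apoe4
  X <- cbind(intercept = 1, dose = r$dose, age = r$age - mean(r$age),
             sex = r$sex)
  if (model == "+apoe4") X <- cbind(X, apoe4 = apoe)
  if (model == "+hcy") X <- cbind(X, hcy = r$hcy)
  if (model == "+folate") X <- cbind(X, folate = r$folate)
  if (model == "+apoe4_interaction")
    X <- cbind(X, apoe4 = apoe, dose_x_apoe4 = r$dose * apoe)
  if (var(X[, "dose"]) == 0)
    stop("column 'dose' has zero variance in the retained subjects")
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  new("DesignMatrix", X = X, subjectIds = as.character(r$subject_id),
      droppedIds = dropped, model = model)
}

# Stack a list of ChangeMaps (or 3D arrays) into an n x V matrix over mask.
stackMaps <- function(maps, mask) {
  vals <- vapply(maps, function(m) {
    a <- if (is(m, "ChangeMap")) changeValues(m) else m
    as.double(a[mask])
  }, numeric(sum(mask)))
  t(vals)
}

#' Mass-univariate OLS of change maps on a design
#'
#' Fits ordinary least squares at every masked voxel with a shared
#' pseudoinverse: betas, standard errors, t statistics and two-sided
#' p-values from the exact t distribution with \code{df = n - k}. Voxels
#' whose response is constant across subjects are flagged invalid (their
#' maps are NA and they are excluded from any subsequent FDR count).
#'
#' @param stack list of n aligned \linkS4class{ChangeMap}s (or 3D
#'   arrays), ordered as the design rows, or an already-stacked
#'   \code{n x V} matrix over the mask.
#' @param design a \linkS4class{DesignMatrix}.
#' @param mask logical 3D array selecting analysis voxels.
#' @param subjectIds optional ids aligned with \code{stack}, checked
#'   against the design rows.
#' @return a \linkS4class{StatMapSet}.
#' @export
fitVoxelwise <- function(stack, design, mask, subjectIds = NULL) {
  X <- designMatrix(design)
  if (!is.null(subjectIds)) {
    if (!identical(as.character(subjectIds), design@subjectIds))
      stop("stack rows do not align with design rows (subject id mismatch)")
  }
  Y <- if (is.matrix(stack)) stack else stackMaps(stack, mask)
  if (nrow(Y) != nrow(X))
    stop("stack has ", nrow(Y), " rows but design has ", nrow(X))
  n <- nrow(X); k <- ncol(X); df <- n - k
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)              # k x V
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / df
  degenerate <- apply(Y, 2, function(col) max(col) - min(col) == 0)
  d <- dim(mask)
  toMap <- function(v) {
    a <- array(NA_real_, dim = d)
    a[mask] <- v
    a
  }
  preds <- colnames(X)
  beta <- se <- tstat <- pval <- stats::setNames(vector("list", k), preds)
  for (i in seq_len(k)) {
    b <- B[i, ]
    s <- sqrt(sigma2 * XtXinv[i, i])
    tv <- ifelse(s > 0, b / s, NA_real_)
    pv <- 2 * pt(-abs(tv), df)
    b[degenerate] <- NA_real_; s[degenerate] <- NA_real_
    tv[degenerate] <- NA_real_; pv[degenerate] <- NA_real_
    beta[[i]] <- toMap(b); se[[i]] <- toMap(s)
    tstat[[i]] <- toMap(tv); pval[[i]] <- toMap(pv)
  }
  valid <- array(FALSE, dim = d)
  valid[mask] <- !degenerate
  s2 <- toMap(ifelse(degenerate, NA_real_, sigma2))
  new("StatMapSet", predictors = preds, beta = beta, se = se,
      tstat = tstat, pval = pval, sigma2 = s2, df = df, n = as.integer(n),
      mask = mask, valid = valid)
}

#' Attenuation of the dose effect under covariate adjustment
#'
#' Compares the mean absolute dose beta over a region between a base fit
#' and an adjusted fit (e.g. adding homocysteine). Under full mediation
#' the adjusted coefficient collapses toward zero and the ratio falls
#' well below 1.
#'
#' @param fitBase,fitAdjusted \linkS4class{StatMapSet}s on the same grid.
#' @param region logical 3D array.
#' @param predictor predictor to compare (default \code{"dose"}).
#' @return list with \code{meanAbsBase}, \code{meanAbsAdjusted},
#'   \code{ratio} (adjusted / base).
#' @export
attenuationReport <- function(fitBase, fitAdjusted, region,
                              predictor = "dose") {
  if (!identical(dim(fitBase@mask), dim(fitAdjusted@mask)))
    stop("fits are on different grids")
  if (sum(region) == 0L) stop("region is empty")
  b0 <- statMap(fitBase, predictor, "beta")
  b1 <- statMap(fitAdjusted, predictor, "beta")
  sel <- region & fitBase@valid & fitAdjusted@valid
  if (sum(sel) == 0L) stop("no valid voxels in region")
  m0 <- mean(abs(b0[sel]))
  m1 <- mean(abs(b1[sel]))
  list(meanAbsBase = m0, meanAbsAdjusted = m1, ratio = m1 / m0,
       nVoxels = sum(sel))
}
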