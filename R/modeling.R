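#' Pearson correlation screening against PNC
#'
#' Pearson r of every feature column against plant nitrogen content, with
#' the two-sided t-test p-value (df = n - 2) and a significance flag at
#' alpha = 0.01.  No multiple-testing correction is applied.
#'
#' @param features data frame or matrix of numeric feature columns.
#' @param pnc numeric response vector, same length.
#' @return data frame \code{feature, r, p_value, significant}; features
#'   with zero variance get NA and \code{significant = FALSE}.
#' @export
pearson_screen <- function(features, pnc) {
  features <- as.data.frame(features)
  if (nrow(features) != length(pnc)) stop("features and pnc lengths differ")
  if (length(pnc) < 3L) stop("need at least 3 paired observations")
  out <- data.frame(feature = names(features), r = NA_real_,
                    p_value = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(features)) {
    x <- features[[i]]
    ok <- is.finite(x) & is.finite(pnc)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(pnc[ok]) == 0) next
    ct <- cor.test(x[ok], pnc[ok], method = "pearson",
                   alternative = "two.sided")
    out$r[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
    out$significant[i] <- ct$p.value < 0.01
  }
  out
}

#' Select the top-k vegetation indices by |r|
#'
#' Keeps only rows of the correlation table whose feature is a registry
#' vegetation index, orders them by decreasing absolute correlation
#' (ties broken by registry order) and returns the first \code{k} names.
#' Morphological parameters are never selected by this operation.
#'
#' @param table output of \code{\link{pearson_screen}}.
#' @param k number of indices to keep (default 5).
#' @return character vector of \code{k} index names.
#' @export
select_top_vis <- function(table, k = 5L) {
  reg <- vi_registry()
  tab <- table[table$feature %in% reg & is.finite(table$r), ]
  if (nrow(tab) < k)
    stop("fewer than ", k, " vegetation indices with finite correlations")
  ord <- order(-abs(tab$r), match(tab$feature, reg))
  tab$feature[ord][seq_len(k)]
}

#' Replication-based train/validation split
#'
#' Replicates 1 and 3 form the calibration (training) set and replicate 2
#' the validation set — the fixed split used throughout the modelling
#' stage (48 plots -> 32 training / 16 validation).
#'
#' @param records data frame with a \code{replication} column (1--3), or a
#'   \code{\link{plot_layer}}.
#' @return list with logical vectors \code{train} and \code{validation}.
#' @export
split_by_replication <- function(records) {
  if (inherits(records, "plot_layer")) records <- records$records
  rep <- records$replication
  if (is.null(rep) || any(is.na(rep))) stop("missing replication labels")
  train <- rep %in% c(1L, 3L)
  validation <- rep == 2L
  if (!any(train)) stop("empty training set: no plots in replicates 1 or 3")
  if (!any(validation)) stop("empty validation set: no plots in replicate 2")
  list(train = train, validation = validation)
}

#' Fit a PNC regression model
#'
#' Three estimators behind one interface: \code{"MLR"} is ordinary least
#' squares with intercept; \code{"KNN"} is k-nearest-neighbour regression
#' (uniform weights, Euclidean distance, default k = 5) on features
#' z-scored with training-set means and SDs; \code{"RF"} is a random
#' forest with 500 trees and \code{ceiling(p/3)} candidate features per
#' split, seeded for reproducibility.
#'
#' @param method \code{"MLR"}, \code{"KNN"} or \code{"RF"}.
#' @param X data frame of numeric features (training rows).
#' @param y numeric response.
#' @param hyper optional list: \code{k} (KNN), \code{ntree}, \code{mtry}
#'   (RF).
#' @param seed integer seed (used by RF's bootstrap).
#' @return a \code{pnc_model} object with a \code{predict} method.
#' @export
fit_model <- function(method = c("MLR", "KNN", "RF"), X, y,
                      hyper = list(), seed = 1L) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  n <- nrow(X); p <- ncol(X)
  fit <- scaling <- NULL
  if (method == "MLR") {
    if (n <= p) stop("MLR needs more training rows than features")
    dat <- cbind(X, .y = y)
    fit <- lm(.y ~ ., data = dat)
    if (qr(fit)$rank < p + 1L) stop("singular design matrix")
  } else if (method == "KNN") {
    k <- hyper$k %||% 5L
    if (k > n) stop("k exceeds the number of training samples")
    mu <- vapply(X, mean, numeric(1))
    sg <- vapply(X, sd, numeric(1)); sg[sg == 0] <- 1
    scaling <- list(mu = mu, sg = sg)
    Xs <- as.data.frame(scale(X, center = mu, scale = sg))
    fit <- caret::knnreg(Xs, y, k = k)
  } else {
    ## canonical row order makes the seeded bootstrap invariant to the
    ## order training rows happen to arrive in
    ord <- do.call(order, as.list(X))
    X <- X[ord, , drop = FALSE]; y <- y[ord]
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(
      x = X, y = y, ntree = hyper$ntree %||% 500L,
      mtry = hyper$mtry %||% ceiling(p / 3))
  }
  structure(list(method = method, fit = fit, scaling = scaling,
                 features = names(X)),
            class = "pnc_model")
}

#' @export
predict.pnc_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  if (object$method == "MLR") {
    as.numeric(predict(object$fit, newdata))
  } else if (object$method == "KNN") {
    Xs <- as.data.frame(scale(newdata, center = object$scaling$mu,
                              scale = object$scaling$sg))
    as.numeric(predict(object$fit, Xs))
  } else {
    as.numeric(predict(object$fit, newdata))
  }
}

#' Regression accuracy metrics
#'
#' \code{R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)} (so validation
#' R2 can be negative), \code{RMSE = sqrt(mean((y - yhat)^2))} in the
#' units of the response, and \code{NRMSE = RMSE / mean(y) * 100} —
#' normalisation by the mean of the observed values, in percent.
#'
#' @param y_obs observed values (length >= 2).
#' @param y_pred predicted values.
#' @return named list \code{R2, RMSE, NRMSE}; R2 is NA (with a warning)
#'   when the observations have zero variance.
#' @export
regression_metrics <- function(y_obs, y_pred) {
  if (length(y_obs) < 2L || length(y_obs) != length(y_pred))
    stop("need >= 2 paired observations")
  ss_res <- sum((y_obs - y_pred)^2)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (ss_tot == 0) warning("zero variance in observations: R2 undefined")
  rmse <- sqrt(ss_res / length(y_obs))
  list(R2 = r2, RMSE = rmse,
       NRMSE = if (mean(y_obs) != 0) rmse / mean(y_obs) * 100 else NA_real_)
}

#' Evaluate a fitted model on a data partition
#'
#' @param model a \code{pnc_model}.
#' @param X feature data frame.
#' @param y_obs observed response.
#' @return named list \code{R2, RMSE, NRMSE} (see
#'   \code{\link{regression_metrics}}).
#' @export
evaluate <- function(model, X, y_obs) {
  regression_metrics(y_obs, predict(model, X))
}

#' Summary statistics in trial-report layout
#'
#' Max, min, mean, sample standard deviation (n - 1 denominator) and the
#' coefficient of variation \code{CV\% = SD / mean * 100}.
#'
#' @param values numeric vector, length >= 2.
#' @return named numeric vector \code{max, min, mean, sd, cv_pct}.
#' @export
summarize_ground_truth <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 values")
  m <- mean(v); s <- sd(v)
  if (m == 0) warning("mean is zero: CV% undefined")
  c(max = max(v), min = min(v), mean = m, sd = s,
    cv_pct = if (m != 0) s / m * 100 else NA_real_)
}

mp_names <- function() c("H", "CC", "CV")

#' Run the full stage x method x feature-set model suite
#'
#' For every growth stage and requested feature set, splits the plots by
#' replication, selects the top-k vegetation indices on the
#' \emph{training} correlations (avoiding selection leakage into the
#' validation set), fits each method and evaluates both partitions.
#' Feature sets: \code{"VIs"} = top-k selected indices; \code{"MPs"} =
#' H, CC, CV; \code{"VIs+MPs"} = their union; \code{"H"}, \code{"CC"},
#' \code{"CV"} = single morphological parameters.
#'
#' @param features data frame with columns \code{plot_id}, \code{stage},
#'   \code{replication}, the registry indices, \code{H}, \code{CC},
#'   \code{CV} and the response \code{PNC}.
#' @param stages stages to model.
#' @param methods subset of \code{c("MLR", "KNN", "RF")}.
#' @param feature_sets which feature sets to fit.
#' @param k_top how many indices \code{"VIs"} keeps.
#' @param seed integer seed (RF bootstrap).
#' @return data frame of class \code{model_report}: one row per stage x
#'   method x feature set x partition with \code{R2, RMSE, NRMSE, n}.
#' @export
run_model_suite <- function(features, stages = c("S1", "S2", "S3"),
                            methods = c("MLR", "KNN", "RF"),
                            feature_sets = c("VIs", "MPs", "VIs+MPs"),
                            k_top = 5L, seed = 1L) {
  rows <- list()
  for (st in stages) {
    dat <- features[features$stage == st, ]
    if (!nrow(dat)) stop("no feature rows for stage ", st)
    if (anyNA(dat$PNC)) stop("missing PNC for stage ", st, " plots: ",
                             paste(dat$plot_id[is.na(dat$PNC)], collapse = ", "))
    sp <- split_by_replication(dat)
    vi_cols <- intersect(vi_registry(), names(dat))
    screen <- pearson_screen(dat[sp$train, vi_cols, drop = FALSE],
                             dat$PNC[sp$train])
    top_vi <- select_top_vis(screen, k = k_top)
    for (fs in feature_sets) {
      cols <- switch(fs,
        "VIs" = top_vi,
        "MPs" = mp_names(),
        "VIs+MPs" = c(top_vi, mp_names()),
        { if (!fs %in% names(dat)) stop("unknown feature set: ", fs); fs })
      for (me in methods) {
        mod <- fit_model(me, dat[sp$train, cols, drop = FALSE],
                         dat$PNC[sp$train], seed = seed)
        for (part in c("calibration", "validation")) {
          idx <- if (part == "calibration") sp$train else sp$validation
          met <- evaluate(mod, dat[idx, cols, drop = FALSE], dat$PNC[idx])
          rows[[length(rows) + 1L]] <- data.frame(
            stage = st, method = me, feature_set = fs, partition = part,
            n = sum(idx), R2 = met$R2, RMSE = met$RMSE, NRMSE = met$NRMSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_report", "data.frame")
  out
}
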