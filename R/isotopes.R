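#' Delta notation for an isotope ratio
#'
#' Per-mil deviation of a sample ratio from the standard:
#' 1000 * (R_sample / R_standard - 1).
#'
#' @param r_sample,r_standard isotope ratios (e.g. 15N/14N), > 0.
#' @return delta value, per mil.
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0))
    stop("isotope ratios must be positive")
  1000 * (r_sample / r_standard - 1)
}

#' Fit a linear discriminant classifier on feather isotopes
#'
#' Two-variable (d15N, d13C) LDA in classification-function form: per class
#' g the linear score a_g . x + c_g with a_g = S^-1 m_g and
#' c_g = -1/2 m_g' S^-1 m_g + log(prior_g), where S is the pooled
#' within-class covariance (divisor n - g) and m_g the class mean. Priors
#' are equal (uninformative) by default; a sample is assigned to the class
#' with the largest score.
#'
#' @param samples data.frame with `d15N`, `d13C` and the label column.
#' @param label_by name of the label column (e.g. "area" or "colony").
#' @param priors class prior probabilities (default equal).
#' @return object of class `isotope_lda`: list with `labels`, `means`,
#'   `pooled_cov`, `priors`, `coef` (matrix classes x 3: d15N, d13C,
#'   constant).
#' @export
fit_lda <- function(samples, label_by = "area", priors = NULL) {
  lab <- as.character(samples[[label_by]])
  classes <- unique(lab)
  g <- length(classes)
  if (g < 2L) stop("need at least 2 classes")
  n_k <- table(factor(lab, levels = classes))
  if (any(n_k < 3L)) stop("every class needs at least 3 samples")
  X <- as.matrix(samples[, c("d15N", "d13C")])
  n <- nrow(X)
  means <- t(vapply(classes, function(k) colMeans(X[lab == k, , drop = FALSE]),
                    numeric(2)))
  SS <- Reduce(`+`, lapply(classes, function(k) {
    Z <- sweep(X[lab == k, , drop = FALSE], 2, means[k, ])
    crossprod(Z)
  }))
  S <- SS / (n - g)
  if (abs(det(S)) < 1e-12) stop("singular pooled covariance")
  Sinv <- solve(S)
  if (is.null(priors)) priors <- rep(1 / g, g)
  stopifnot(length(priors) == g, abs(sum(priors) - 1) < 1e-8)
  coef <- t(vapply(seq_len(g), function(i) {
    a <- Sinv %*% means[i, ]
    c(a, -0.5 * drop(t(means[i, ]) %*% Sinv %*% means[i, ]) + log(priors[i]))
  }, numeric(3)))
  dimnames(coef) <- list(classes, c("d15N", "d13C", "constant"))
  structure(list(labels = classes, means = means, pooled_cov = S,
                 priors = priors, coef = coef),
            class = "isotope_lda")
}

#' Evaluate linear classification functions
#'
#' Scores each sample under each class's linear function. Works for fitted
#' models and for published coefficient tables alike.
#'
#' @param coef matrix (classes x 3: coefficient on d15N, coefficient on
#'   d13C, constant), or an `isotope_lda`.
#' @param d15N,d13C numeric vectors.
#' @return matrix of scores, samples x classes.
#' @export
discriminant_scores <- function(coef, d15N, d13C) {
  if (inherits(coef, "isotope_lda")) coef <- coef$coef
  cbind(d15N, d13C, 1) %*% t(coef)
}

#' @param object an `isotope_lda`.
#' @param newdata data.frame with `d15N`, `d13C`.
#' @param ... unused.
#' @return character vector of assigned class labels.
#' @rdname fit_lda
#' @export
predict.isotope_lda <- function(object, newdata, ...) {
  sc <- discriminant_scores(object$coef, newdata$d15N, newdata$d13C)
  ties <- apply(sc, 1L, function(r) sum(r == max(r)) > 1L)
  if (any(ties)) warning("tied scores; assigned to the first class")
  object$labels[max.col(sc, ties.method = "first")]
}

#' @param x an `isotope_lda`.
#' @rdname fit_lda
#' @export
print.isotope_lda <- function(x, ...) {
  cat("Linear discriminant classification functions (d15N, d13C):\n")
  for (i in seq_along(x$labels)) {
    b <- x$coef[i, ]
    cat(sprintf("  %-16s %.1f x d15N %s %.1f x d13C %s %.1f\n", x$labels[i],
                b[1], ifelse(b[2] < 0, "-", "+"), abs(b[2]),
                ifelse(b[3] < 0, "-", "+"), abs(b[3])))
  }
  invisible(x)
}

#' Published discriminant functions for non-breeding areas
#'
#' The reference classification functions for assigning Bulwer's petrels to
#' their Atlantic non-breeding areas from S8 or R6 feather isotopes. For a
#' bird, the class whose function gives the higher value is the assigned
#' area.
#'
#' @param feather "S8" or "R6".
#' @return coefficient matrix (classes x 3) usable with
#'   [discriminant_scores()].
#' @export
reference_discriminant_functions <- function(feather = c("S8", "R6")) {
  feather <- match.arg(feather)
  m <- if (feather == "S8") {
    rbind(CentralAtlantic = c(5.8, -116.2, -983.7),
          SouthAtlantic   = c(7.0, -118.8, -1043.9))
  } else {
    rbind(CentralAtlantic = c(1.3, -79.0, -660.9),
          SouthAtlantic   = c(2.3, -82.2, -727.1))
  }
  colnames(m) <- c("d15N", "d13C", "constant")
  m
}

#' 70/30 train/test split with one record per bird in training
#'
#' The training pool starts with one randomly chosen record per bird (birds
#' tracked several years contribute one); every other record goes to
#' testing. Then, per class, if fewer than `1 - train_frac` of the class's
#' records are in testing, randomly chosen records are moved from training
#' to testing until that share is reached.
#'
#' @param samples data.frame with `bird_id` and the class column.
#' @param label_by class column name.
#' @param train_frac training fraction (default 0.70).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(samples, label_by = "area", train_frac = 0.70,
                             seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  lab <- as.character(samples[[label_by]])
  if (any(table(lab) < 2L)) stop("every class needs at least 2 records")
  set.seed(seed)
  idx <- seq_len(nrow(samples))
  # one record per bird into the training pool
  train_idx <- unlist(lapply(split(idx, samples$bird_id), function(i)
    if (length(i) == 1L) i else sample(i, 1L)))
  in_train <- idx %in% train_idx
  for (k in unique(lab)) {
    ki <- which(lab == k)
    need_test <- ceiling(length(ki) * (1 - train_frac) - 1e-9)
    short <- need_test - sum(!in_train[ki])
    if (short > 0L) {
      pool <- ki[in_train[ki]]
      move <- if (length(pool) == 1L) pool else sample(pool, short)
      in_train[move] <- FALSE
    }
  }
  list(train = samples[in_train, , drop = FALSE],
       test = samples[!in_train, , drop = FALSE])
}

#' Correct classification rates for training and testing data
#'
#' Per-class percent-correct on the training and testing sets of a fitted
#' classifier, with totals computed as sample-size-weighted means of the
#' class rates.
#'
#' @param model an `isotope_lda` fitted on `train` only.
#' @param train,test data.frames with `d15N`, `d13C` and the class column.
#' @param label_by class column name.
#' @return data.frame (class `confusion_summary`) with one row per class
#'   plus a `Total` row: `class`, `n_train`, `n_test`, `pct_train`,
#'   `pct_test`.
#' @export
classification_rates <- function(model, train, test, label_by = "area") {
  classes <- model$labels
  if (any(!table(factor(test[[label_by]], levels = classes)) > 0))
    stop("empty test class")
  rate <- function(d) {
    pred <- predict(model, d)
    obs <- as.character(d[[label_by]])
    vapply(classes, function(k)
      100 * mean(pred[obs == k] == k), numeric(1))
  }
  n_tr <- as.integer(table(factor(train[[label_by]], levels = classes)))
  n_te <- as.integer(table(factor(test[[label_by]], levels = classes)))
  out <- data.frame(class = classes, n_train = n_tr, n_test = n_te,
                    pct_train = rate(train), pct_test = rate(test),
                    stringsAsFactors = FALSE, row.names = NULL)
  rbind_total(out)
}

#' Weighted total row of a classification-rate table
#'
#' Appends a `Total` row whose rates are the sample-size-weighted means of
#' the per-class rates.
#'
#' @param rates data.frame with `class`, `n_train`, `n_test`, `pct_train`,
#'   `pct_test`.
#' @return the table with a `Total` row, class `confusion_summary`.
#' @export
rbind_total <- function(rates) {
  tot <- data.frame(class = "Total",
                    n_train = sum(rates$n_train), n_test = sum(rates$n_test),
                    pct_train = sum(rates$n_train * rates$pct_train) /
                      sum(rates$n_train),
                    pct_test = sum(rates$n_test * rates$pct_test) /
                      sum(rates$n_test),
                    stringsAsFactors = FALSE)
  out <- rbind(rates[rates$class != "Total", ], tot)
  class(out) <- c("confusion_summary", "data.frame")
  out
}

#' Compare isotope values among groups
#'
#' One-way ANOVA with Tukey HSD post-hoc letters for parametric data, or a
#' tie-corrected Kruskal-Wallis test with Dunn's post-hoc (Bonferroni) for
#' non-parametric data. With `test = "auto"` the Kruskal-Wallis route is
#' taken when any group fails a Shapiro-Wilk normality check at alpha.
#'
#' @param values numeric response (e.g. d15N).
#' @param groups group factor.
#' @param test "auto", "anova" or "kruskal".
#' @param alpha significance level for post-hoc letters and the normality
#'   screen (default 0.05).
#' @return list with `test`, `statistic`, `df`, `p_value`, `letters`
#'   (named per group; groups sharing no letter differ at alpha).
#' @export
group_comparison <- function(values, groups, test = c("auto", "anova", "kruskal"),
                             alpha = 0.05) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("every group needs at least 3 observations")
  if (test == "auto") {
    norm_ok <- vapply(levels(groups), function(g) {
      x <- values[groups == g]
      if (stats::sd(x) == 0) return(TRUE)
      stats::shapiro.test(x)$p.value >= alpha
    }, logical(1))
    test <- if (all(norm_ok)) "anova" else "kruskal"
  }
  if (test == "anova") {
    if (any(tapply(values, groups, stats::sd) == 0))
      warning("a group has zero variance; F statistic may be unstable")
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    tk <- stats::TukeyHSD(fit)$groups
    pmat <- .pairwise_p_matrix(rownames(tk), tk[, "p adj"], levels(groups))
    list(test = "anova", statistic = an[1L, "F value"],
         df = an$Df[1:2], p_value = an[1L, "Pr(>F)"],
         letters = .letter_display(pmat, alpha))
  } else {
    kw <- stats::kruskal.test(values, groups)
    dunn <- dunn_posthoc(values, groups)
    pmat <- .pairwise_p_matrix(dunn$pair, dunn$p_adj, levels(groups))
    list(test = "kruskal", statistic = unname(kw$statistic),
         df = unname(kw$parameter), p_value = kw$p.value,
         letters = .letter_display(pmat, alpha))
  }
}

#' Dunn's post-hoc test on ranks
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with a
#' tie correction and Bonferroni-adjusted p-values.
#'
#' @param values numeric response.
#' @param groups group factor.
#' @return data.frame `pair` ("a-b"), `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  res <- apply(combs, 2L, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sum(i) + 1 / sum(j)))
    z <- (mean(r[i]) - mean(r[j])) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  p_adj <- pmin(1, res["p", ] * ncol(combs))
  data.frame(pair = paste(combs[1, ], combs[2, ], sep = "-"),
             z = res["z", ], p = res["p", ], p_adj = p_adj,
             stringsAsFactors = FALSE, row.names = NULL)
}

# square matrix of pairwise adjusted p-values from "a-b" labels
.pairwise_p_matrix <- function(pairs, p, levels) {
  m <- matrix(1, length(levels), length(levels),
              dimnames = list(levels, levels))
  for (i in seq_along(pairs)) {
    ab <- strsplit(pairs[i], "-", fixed = TRUE)[[1L]]
    m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- p[i]
  }
  m
}

# compact letter display by insert-and-absorb
.letter_display <- function(pmat, alpha) {
  g <- rownames(pmat)
  sets <- list(g)
  combs <- utils::combn(g, 2)
  for (c_i in seq_len(ncol(combs))) {
    a <- combs[1, c_i]; b <- combs[2, c_i]
    if (!isTRUE(pmat[a, b] < alpha)) next  # NA/NaN p treated as no evidence
    for (s_i in rev(seq_along(sets))) {
      s <- sets[[s_i]]
      if (all(c(a, b) %in% s)) {
        sets[[s_i]] <- NULL
        cand <- list(setdiff(s, a), setdiff(s, b))
        for (cs in cand) {
          absorbed <- any(vapply(sets, function(t) all(cs %in% t), logical(1)))
          if (!absorbed) sets <- c(sets, list(cs))
        }
      }
    }
  }
  out <- vapply(g, function(x) paste(letters[which(vapply(sets, function(s)
    x %in% s, logical(1)))], collapse = ""), character(1))
  out
}

#' Standard ellipse area of an isotopic niche
#'
#' The standard ellipse of a bivariate (d15N, d13C) sample has area
#' SEA = pi * sqrt(lambda1 * lambda2) from the covariance eigenvalues;
#' SEAc = SEA * (n - 1) / (n - 2) corrects for small samples. Optionally
#' draws from the conjugate normal-inverse-Wishart posterior of the
#' covariance (vague prior), mapping each draw to an SEA, to give a
#' posterior distribution of ellipse areas.
#'
#' @param x matrix or data.frame with 2 columns (d15N, d13C), n >= 3 rows.
#' @param bayesian draw posterior SEAs?
#' @param n_draws number of posterior draws.
#' @param seed RNG seed for the posterior draws.
#' @return list with `n`, `SEA`, `SEAc`, `semi_axes` (sqrt eigenvalues),
#'   `orientation` (radians), and `posterior_SEA` (numeric vector) when
#'   `bayesian = TRUE`.
#' @export
standard_ellipse <- function(x, bayesian = FALSE, n_draws = 1000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(ncol(x) == 2L, n >= 3L)
  S <- stats::cov(x)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-12) stop("degenerate (collinear) sample")
  sea <- pi * sqrt(prod(e$values))
  out <- list(n = n, SEA = sea, SEAc = sea * (n - 1) / (n - 2),
              semi_axes = sqrt(e$values),
              orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]))
  if (bayesian) {
    set.seed(seed)
    # vague NIW prior: nu0 = d + 1 = 3, scale = 0.01 * sample covariance
    nu_n <- 3 + n
    Lambda_n <- 0.01 * S + crossprod(sweep(x, 2, colMeans(x)))
    draws <- stats::rWishart(n_draws, nu_n, solve(Lambda_n))
    out$posterior_SEA <- apply(draws, 3, function(W) {
      Sd <- solve(W)
      pi * sqrt(det(Sd))
    })
  }
  out
}

#' Per-feather isotope variability across colonies
#'
#' Mean and SD of each isotope per feather and colony, with a
#' moult-chronology screen: feathers whose pooled SD exceeds
#' `sd_multiple` times the pooled SD of P1 are flagged as grown across
#' heterogeneous areas.
#'
#' @param samples corpse feather table (`colony`, `feather`, `d15N`,
#'   `d13C`).
#' @param sd_multiple flag threshold as a multiple of the P1 pooled SD
#'   (default 1.5).
#' @return list with `by_colony` (feather x colony means/SDs) and `flags`
#'   (data.frame `feather`, `pooled_sd_d15N`, `flagged`).
#' @export
feather_variability_summary <- function(samples, sd_multiple = 1.5) {
  agg <- stats::aggregate(cbind(d15N, d13C) ~ feather + colony, samples,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  by_colony <- data.frame(feather = agg$feather, colony = agg$colony,
                          mean_d15N = agg$d15N[, "mean"],
                          sd_d15N = agg$d15N[, "sd"],
                          mean_d13C = agg$d13C[, "mean"],
                          sd_d13C = agg$d13C[, "sd"],
                          stringsAsFactors = FALSE)
  pooled <- stats::aggregate(d15N ~ feather, samples, stats::sd)
  names(pooled)[2] <- "pooled_sd_d15N"
  ref <- pooled$pooled_sd_d15N[pooled$feather == "P1"]
  if (length(ref) == 0L) stop("corpse sequence must include P1")
  pooled$flagged <- pooled$pooled_sd_d15N > sd_multiple * ref
  list(by_colony = by_colony, flags = pooled)
}
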