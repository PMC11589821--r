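# Interval-mapping scan engines.
#
# All three engines share a precomputed grid of putative-QTL "designs":
# at every walking-step position the expected QTL genotype is computed
# from the flanking markers through the no-interference Markov chain
# (Haley-Knott regression). The LOD at a position is the regression LOD
# (n/2) * log10(RSS0 / RSS1).

# Conditional P(QTL genotype | flanking F2 genotypes) by enumerating the
# two gamete haplotypes. gl, gr are B-allele counts 0/1/2 or NA (missing
# flank). r1, r2 are the recombination fractions to the left and right
# flank. Returns the 3-vector (P(AA), P(AH), P(BB)).
f2_cond_probs <- function(gl, gr, r1, r2) {
  trans <- function(a, b, r) ifelse(a == b, 1 - r, r)
  p <- numeric(3)
  for (l1 in 0:1) for (q1 in 0:1) for (x1 in 0:1) {
    p1 <- 0.5 * trans(l1, q1, r1) * trans(q1, x1, r2)
    for (l2 in 0:1) for (q2 in 0:1) for (x2 in 0:1) {
      if (!is.na(gl) && l1 + l2 != gl) next
      if (!is.na(gr) && x1 + x2 != gr) next
      p2 <- 0.5 * trans(l2, q2, r1) * trans(q2, x2, r2)
      p[q1 + q2 + 1] <- p[q1 + q2 + 1] + p1 * p2
    }
  }
  p / sum(p)
}

# RIL analogue over a single homozygous genome; the chain uses the
# selfed-RIL expanded fractions r* = 2r/(1+2r) (standard Markov
# approximation for positions inside an interval). Returns (P(AA), 0,
# P(BB)).
ril_cond_probs <- function(gl, gr, r1, r2) {
  rs1 <- 2 * r1 / (1 + 2 * r1)
  rs2 <- 2 * r2 / (1 + 2 * r2)
  trans <- function(a, b, r) if (a == b) 1 - r else r
  p <- numeric(2)
  for (q in 0:1) {
    w <- 0.5
    if (!is.na(gl)) w <- w * trans(gl / 2, q, rs1)
    if (!is.na(gr)) w <- w * trans(q, gr / 2, rs2)
    p[q + 1] <- w
  }
  p <- p / sum(p)
  c(p[1], 0, p[2])
}

# Build the per-position design table for one pair of flanking genotype
# columns. Returns x_add (E[geno]-1), x_dom (P(het)), keep mask.
position_design <- function(gl_vec, gr_vec, r1, r2, population) {
  keep <- !(is.na(gl_vec) & is.na(gr_vec))
  combos <- unique(cbind(gl_vec, gr_vec))
  x_add <- rep(NA_real_, length(gl_vec))
  x_dom <- rep(NA_real_, length(gl_vec))
  for (i in seq_len(nrow(combos))) {
    gl <- combos[i, 1]
    gr <- combos[i, 2]
    hit <- (gl_vec %in% gl | (is.na(gl_vec) & is.na(gl))) &
      (gr_vec %in% gr | (is.na(gr_vec) & is.na(gr)))
    pr <- if (population == "F2") f2_cond_probs(gl, gr, r1, r2) else
      ril_cond_probs(gl, gr, r1, r2)
    x_add[hit] <- pr[3] - pr[1]
    x_dom[hit] <- pr[2]
  }
  list(x_add = x_add, x_dom = x_dom, keep = keep)
}

#' Precompute the Haley-Knott scan grid for a map and genotype matrix
#'
#' Builds, once per dataset, the expected-genotype regression design at
#' every grid position (walking step `step_cM` within each linkage group,
#' last marker always included). The result can be passed to the scan
#' functions to avoid recomputation across genes and permutations.
#'
#' @param map a `genetic_map` from [build_map()] (or any data frame with
#'   `linkage_group`, `marker_id`, `chrom`, `pos_bp`, `pos_cM`).
#' @param genotypes lines x markers character matrix.
#' @param population `"F2"` or `"RIL"`; F2 designs carry an additive and a
#'   dominance column, RIL only additive.
#' @param step_cM walking step (default 1 cM).
#' @return an object of class `scan_designs`: `positions` data frame plus
#'   internal per-position QR factors.
#' @export
scan_designs <- function(map, genotypes, population = c("F2", "RIL"),
                         step_cM = 1) {
  population <- match.arg(population)
  num <- geno_to_numeric(genotypes[, map$marker_id, drop = FALSE])
  pos_rows <- list()
  designs <- list()
  for (lg in unique(map$linkage_group)) {
    sub <- map[map$linkage_group == lg, , drop = FALSE]
    m <- nrow(sub)
    cM <- sub$pos_cM
    # walking-step grid plus every marker position (so marker LODs are
    # exact regressions on the observed genotypes)
    grid <- sort(unique(c(seq(cM[1], cM[m], by = step_cM), cM)))
    for (pos in grid) {
      if (m == 1) {
        i <- 1
        gl <- num[, sub$marker_id[1]]
        gr <- rep(NA_real_, nrow(num))
        r1 <- r2 <- 0
        left_i <- right_i <- 1
      } else {
        i <- min(max(findInterval(pos, cM), 1), m - 1)
        gl <- num[, sub$marker_id[i]]
        gr <- num[, sub$marker_id[i + 1]]
        r1 <- kosambi_r(pos - cM[i])
        r2 <- kosambi_r(cM[i + 1] - pos)
        left_i <- i
        right_i <- i + 1
      }
      d <- position_design(gl, gr, r1, r2, population)
      X <- if (population == "F2") cbind(d$x_add, d$x_dom) else
        cbind(d$x_add)
      Xk <- cbind(1, X[d$keep, , drop = FALSE])
      qrx <- qr(Xk)
      designs[[length(designs) + 1]] <- list(
        Q = qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE],
        X = X, keep = d$keep, all_kept = all(d$keep)
      )
      pos_rows[[length(pos_rows) + 1]] <- data.frame(
        linkage_group = lg, chrom = sub$chrom[1], pos_cM = pos,
        left_marker = sub$marker_id[left_i],
        right_marker = sub$marker_id[right_i],
        left_bp = sub$pos_bp[left_i], right_bp = sub$pos_bp[right_i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(positions = do.call(rbind, pos_rows), designs = designs,
              population = population, n_lines = nrow(num),
              marker_ids = map$marker_id, step_cM = step_cM)
  class(out) <- "scan_designs"
  out
}

# LOD at every grid position for each phenotype column of Y (n x g).
# Vectorized across phenotypes: RSS1 = y'y - ||Q'y||^2.
lod_profile_matrix <- function(designs, Y) {
  Y <- as.matrix(Y)
  out <- matrix(0, length(designs$designs), ncol(Y))
  for (k in seq_along(designs$designs)) {
    d <- designs$designs[[k]]
    Yk <- if (d$all_kept) Y else Y[d$keep, , drop = FALSE]
    nk <- nrow(Yk)
    tot <- colSums(Yk^2)
    rss0 <- tot - colSums(Yk)^2 / nk
    rss1 <- tot - colSums(crossprod(d$Q, Yk)^2)
    rss1 <- pmax(rss1, 1e-12)
    lod <- ifelse(rss0 <= 1e-12, 0, (nk / 2) * log10(rss0 / rss1))
    out[k, ] <- pmax(lod, 0)
  }
  out
}

# Effect estimates at one grid position: additive = half the homozygote
# mean difference, dominance = heterozygote deviation, PVE at the peak.
fit_position <- function(designs, k, y) {
  d <- designs$designs[[k]]
  yk <- y[d$keep]
  X <- d$X[d$keep, , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), yk)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((yk - mean(yk))^2)
  co <- fit$coefficients
  list(
    additive = unname(co[2]),
    dominance = if (designs$population == "F2") unname(co[3]) else NA_real_,
    pve = if (rss0 > 0) 100 * (1 - rss1 / rss0) else 0,
    lod = if (rss0 > 0) max((length(yk) / 2) * log10(rss0 / max(rss1, 1e-12)), 0) else 0
  )
}

peak_table <- function(designs, lods, y, threshold, method) {
  pos <- designs$positions
  peaks <- list()
  for (lg in unique(pos$linkage_group)) {
    idx <- which(pos$linkage_group == lg)
    k <- idx[which.max(lods[idx])]
    if (lods[k] < threshold) next
    eff <- fit_position(designs, k, y)
    peaks[[length(peaks) + 1]] <- data.frame(
      method = method, linkage_group = lg, chrom = pos$chrom[k],
      pos_cM = pos$pos_cM[k], left_bp = pos$left_bp[k],
      right_bp = pos$right_bp[k], lod = lods[k], pve = eff$pve,
      additive = eff$additive, dominance = eff$dominance,
      stringsAsFactors = FALSE
    )
  }
  if (length(peaks) == 0) empty_peaks(method) else do.call(rbind, peaks)
}

empty_peaks <- function(method) {
  data.frame(method = character(0), linkage_group = character(0),
             chrom = character(0), pos_cM = numeric(0), left_bp = numeric(0),
             right_bp = numeric(0), lod = numeric(0), pve = numeric(0),
             additive = numeric(0), dominance = numeric(0),
             stringsAsFactors = FALSE)
}

#' Interval-mapping scan for one expression phenotype
#'
#' Haley-Knott regression of the phenotype on the expected QTL genotype at
#' every grid position (`y ~ additive` for RIL, `y ~ additive + dominance`
#' for F2). One peak is reported per linkage group, at the LOD maximum,
#' when it clears `threshold`; peak bounds are the flanking markers'
#' physical positions. A constant phenotype yields an all-zero profile and
#' no peaks.
#'
#' @param phenotype numeric vector, one value per line (normalized
#'   expression of one gene), no missing values.
#' @param map,genotypes,population,step_cM see [scan_designs()]; ignored
#'   when `designs` is supplied.
#' @param threshold LOD threshold for calling a peak (default 3).
#' @param designs optional precomputed [scan_designs()].
#' @return list with `profile` (grid data frame with `lod`) and `peaks`
#'   (one row per called peak: method, linkage group, chromosome, flanking
#'   marker positions, LOD, PVE, additive and dominance effects).
#' @export
im_scan <- function(phenotype, map = NULL, genotypes = NULL,
                    population = c("F2", "RIL"), step_cM = 1,
                    threshold = 3, designs = NULL) {
  if (is.null(designs)) {
    designs <- scan_designs(map, genotypes, match.arg(population), step_cM)
  }
  if (length(phenotype) != designs$n_lines) {
    stop("phenotype length must equal the number of lines", call. = FALSE)
  }
  if (anyNA(phenotype)) stop("phenotype must not contain NA", call. = FALSE)
  lods <- lod_profile_matrix(designs, matrix(phenotype))[, 1]
  profile <- cbind(designs$positions, lod = lods)
  list(profile = profile,
       peaks = peak_table(designs, lods, phenotype, threshold, "IM"))
}

# Forward-backward stepwise marker selection on additive codings;
# entry/exit by partial-F p-values. Returns marker column indices.
stepwise_select <- function(y, M, p_in = 0.001, p_out = 0.002,
                            max_terms = 10) {
  n <- length(y)
  sel <- integer(0)
  repeat {
    changed <- FALSE
    if (length(sel) < max_terms) {
      Xc <- cbind(1, M[, sel, drop = FALSE])
      qX <- qr(Xc)
      ry <- qr.resid(qX, y)
      cand <- setdiff(seq_len(ncol(M)), sel)
      RZ <- qr.resid(qX, M[, cand, drop = FALSE])
      ssz <- colSums(RZ^2)
      ok <- ssz > 1e-10 & sum(ry^2) > 1e-10
      rho2 <- rep(0, length(cand))
      rho2[ok] <- (crossprod(RZ[, ok, drop = FALSE], ry)^2 /
                     (ssz[ok] * sum(ry^2)))
      df2 <- n - length(sel) - 2
      if (df2 > 0 && any(ok)) {
        Fst <- rho2 * df2 / pmax(1 - rho2, 1e-12)
        pv <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
        best <- which.min(pv)
        if (pv[best] < p_in) {
          sel <- c(sel, cand[best])
          changed <- TRUE
        }
      }
    }
    if (length(sel) > 0) {
      fit <- stats::lm.fit(cbind(1, M[, sel, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      df2 <- n - length(sel) - 1
      drop_p <- vapply(seq_along(sel), function(j) {
        fit0 <- stats::lm.fit(cbind(1, M[, sel[-j], drop = FALSE]), y)
        rss0 <- sum(fit0$residuals^2)
        Fst <- (rss0 - rss) / (rss / max(df2, 1))
        stats::pf(Fst, 1, max(df2, 1), lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(drop_p)
      if (drop_p[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sel
}

#' Inclusive composite interval mapping scan
#'
#' Three-stage ICIM: (1) forward-backward stepwise selection of marker
#' cofactors on the phenotype at entry/exit p-values `p_in`/`p_out`;
#' (2) for each scanned interval, the phenotype is adjusted by subtracting
#' the fitted contributions of the selected cofactors, excluding the two
#' markers flanking that interval; (3) an interval-mapping scan of the
#' adjusted phenotype. With no cofactors selected the result equals
#' [im_scan()] exactly.
#'
#' @inheritParams im_scan
#' @param p_in,p_out stepwise entry/exit p-values (defaults 0.001/0.002).
#' @param max_cofactors cap on selected cofactors (default 10).
#' @return as [im_scan()], with method `"ICIM"`.
#' @export
icim_scan <- function(phenotype, map = NULL, genotypes = NULL,
                      population = c("F2", "RIL"), step_cM = 1,
                      p_in = 0.001, p_out = 0.002, threshold = 3,
                      max_cofactors = 10, designs = NULL) {
  if (is.null(designs)) {
    designs <- scan_designs(map, genotypes, match.arg(population), step_cM)
  }
  if (anyNA(phenotype)) stop("phenotype must not contain NA", call. = FALSE)
  M <- marker_matrix_from_designs(designs, genotypes, map)
  sel <- if (stats::sd(phenotype) == 0) integer(0) else
    stepwise_select(phenotype, M, p_in, p_out, max_cofactors)
  if (length(sel) == 0) {
    out <- im_scan(phenotype, threshold = threshold, designs = designs)
    out$peaks$method <- rep("ICIM", nrow(out$peaks))
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, M[, sel, drop = FALSE]), phenotype)
  beta <- fit$coefficients[-1]
  contrib <- sweep(M[, sel, drop = FALSE], 2, beta, "*")
  sel_ids <- colnames(M)[sel]
  pos <- designs$positions
  lods <- numeric(nrow(pos))
  y_store <- vector("list", nrow(pos))
  key <- paste(pos$left_marker, pos$right_marker)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    flank <- c(pos$left_marker[idx[1]], pos$right_marker[idx[1]])
    use <- !(sel_ids %in% flank)
    y_adj <- phenotype - if (any(use))
      rowSums(contrib[, use, drop = FALSE]) else 0
    sub <- designs
    sub$designs <- designs$designs[idx]
    lods[idx] <- lod_profile_matrix(sub, matrix(y_adj))[, 1]
    for (k in idx) y_store[[k]] <- y_adj
  }
  profile <- cbind(pos, lod = lods)
  peaks <- list()
  for (lg in unique(pos$linkage_group)) {
    idx <- which(pos$linkage_group == lg)
    k <- idx[which.max(lods[idx])]
    if (lods[k] < threshold) next
    eff <- fit_position(designs, k, y_store[[k]])
    peaks[[length(peaks) + 1]] <- data.frame(
      method = "ICIM", linkage_group = lg, chrom = pos$chrom[k],
      pos_cM = pos$pos_cM[k], left_bp = pos$left_bp[k],
      right_bp = pos$right_bp[k], lod = lods[k], pve = eff$pve,
      additive = eff$additive, dominance = eff$dominance,
      stringsAsFactors = FALSE
    )
  }
  list(profile = profile,
       peaks = if (length(peaks) == 0) empty_peaks("ICIM") else
         do.call(rbind, peaks))
}

# Additive marker codings (B-count - 1), mean-imputed, for cofactor
# selection and the GCIM marker scan.
marker_matrix_from_designs <- function(designs, genotypes, map) {
  M <- geno_to_numeric(genotypes[, designs$marker_ids, drop = FALSE]) - 1
  for (j in seq_len(ncol(M))) {
    mj <- M[, j]
    if (anyNA(mj)) M[is.na(mj), j] <- mean(mj, na.rm = TRUE)
  }
  M
}

#' Genome-wide composite interval mapping scan (simplified)
#'
#' A two-stage multi-locus scan in the spirit of genome-wide composite
#' interval mapping. Stage 1 is a single-position scan at every marker
#' with a polygenic control: either `"fixed"` (top-`k` marker cofactors by
#' marginal association, excluding cofactors within `exclusion_cM` of the
#' tested marker on the same linkage group) or `"fixed_REML"` (a
#' variance-component polygenic term with a marker-derived kinship, fitted
#' by REML and used to whiten the scan). Stage 2 jointly refits the
#' markers passing a liberal stage-1 cut by lasso-penalized multi-locus
#' regression (model selected by BIC along the lambda path); surviving
#' loci are reported with the LOD of their drop-one likelihood ratio in
#' the joint ordinary-least-squares model.
#'
#' @inheritParams im_scan
#' @param model `"fixed"` or `"fixed_REML"`; a singular kinship falls back
#'   to `"fixed"` with a warning.
#' @param k number of cofactors for the fixed model (default 5; 0 gives a
#'   plain marker-regression scan).
#' @param stage1_lod liberal stage-1 LOD cut for candidates (default 2.5).
#' @param threshold LOD threshold for reported loci (default 4).
#' @param exclusion_cM cofactor exclusion window around the tested marker.
#' @return list with `profile` (marker-level stage-1 LOD) and `peaks`
#'   (reported loci, `left_bp == right_bp ==` marker position).
#' @export
gcim_scan <- function(phenotype, map = NULL, genotypes = NULL,
                      population = c("F2", "RIL"),
                      model = c("fixed", "fixed_REML"), k = 5,
                      stage1_lod = 2.5, threshold = 4, exclusion_cM = 20,
                      designs = NULL, step_cM = 1) {
  model <- match.arg(model)
  if (is.null(designs)) {
    designs <- scan_designs(map, genotypes, match.arg(population), step_cM)
  }
  if (anyNA(phenotype)) stop("phenotype must not contain NA", call. = FALSE)
  if (is.null(map)) stop("gcim_scan needs the map", call. = FALSE)
  M <- marker_matrix_from_designs(designs, genotypes, map)
  n <- nrow(M)
  y <- phenotype
  if (stats::sd(y) == 0) {
    return(list(profile = cbind(map, lod = 0), peaks = empty_peaks("GCIM")))
  }
  lods <- numeric(ncol(M))
  if (model == "fixed_REML") {
    lg_of <- map$linkage_group[match(designs$marker_ids, map$marker_id)]
    ok <- TRUE
    for (lg in unique(lg_of)) {
      inside <- which(lg_of == lg)
      # leave-one-group-out kinship so the polygenic term does not absorb
      # the locus being tested
      wh <- tryCatch(reml_whiten(y, M[, -inside, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(wh)) {
        ok <- FALSE
        break
      }
      yt <- wh$y
      It <- wh$intercept
      rss0 <- gls_rss(yt, It)
      for (j in inside) {
        rss1 <- gls_rss(yt, cbind(It, wh$transform(M[, j])))
        lods[j] <- max((n / 2) * log10(rss0 / max(rss1, 1e-12)), 0)
      }
    }
    if (!ok) {
      warning("singular kinship; falling back to the fixed model",
              call. = FALSE)
      model <- "fixed"
    }
  }
  if (model == "fixed") {
    cof <- if (k > 0) order(-abs(stats::cor(y, M)[1, ]))[seq_len(min(k, ncol(M)))]
      else integer(0)
    for (j in seq_len(ncol(M))) {
      keep_cof <- cof[!cofactor_near(cof, j, map, designs$marker_ids,
                                     exclusion_cM)]
      X0 <- cbind(1, M[, keep_cof, drop = FALSE])
      f0 <- stats::lm.fit(X0, y)
      f1 <- stats::lm.fit(cbind(X0, M[, j]), y)
      rss0 <- sum(f0$residuals^2)
      rss1 <- max(sum(f1$residuals^2), 1e-12)
      lods[j] <- max((n / 2) * log10(rss0 / rss1), 0)
    }
  }
  profile <- cbind(map[, c("linkage_group", "marker_id", "chrom", "pos_bp",
                           "pos_cM")], lod = lods)
  cand <- local_maxima(lods, map, stage1_lod, exclusion_cM)
  peaks <- gcim_stage2(y, M, cand, map, designs, threshold, genotypes)
  list(profile = profile, peaks = peaks)
}

# Thin stage-1 candidates to local LOD maxima: a marker is kept when it
# clears the cut and dominates every marker within the window on its own
# linkage group (ties broken by position). Avoids feeding collinear
# neighbors of one peak into the joint model.
local_maxima <- function(lods, map, cut, window_cM) {
  keep <- integer(0)
  for (j in which(lods >= cut)) {
    near <- which(map$linkage_group == map$linkage_group[j] &
                    abs(map$pos_cM - map$pos_cM[j]) <= window_cM)
    best <- near[which.max(lods[near])]
    if (best == j) keep <- c(keep, j)
  }
  keep
}

cofactor_near <- function(cof, j, map, marker_ids, exclusion_cM) {
  if (length(cof) == 0) return(logical(0))
  lg <- map$linkage_group[match(marker_ids, map$marker_id)]
  cM <- map$pos_cM[match(marker_ids, map$marker_id)]
  same <- lg[cof] == lg[j]
  near <- abs(cM[cof] - cM[j]) <= exclusion_cM
  (cof == j) | (same & near)
}

gls_rss <- function(y, X) {
  fit <- stats::lm.fit(as.matrix(X), y)
  sum(fit$residuals^2)
}

# EMMA-style REML fit of the polygenic variance ratio; returns a
# whitening transform for y, the intercept, and marker columns.
reml_whiten <- function(y, M) {
  n <- length(y)
  Ms <- scale(M)
  Ms[is.na(Ms)] <- 0
  K <- tcrossprod(Ms) / ncol(Ms)
  eg <- eigen(K, symmetric = TRUE)
  if (!all(is.finite(eg$values))) stop("singular kinship")
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  uy <- crossprod(U, y - mean(y))
  reml_nll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- lam + delta
    (n - 1) * log(sum(uy^2 / w)) + sum(log(w))
  }
  opt <- stats::optimize(reml_nll, c(log(1e-4), log(1e4)))
  delta <- exp(opt$minimum)
  wts <- 1 / sqrt(lam + delta)
  transform <- function(v) wts * crossprod(U, v)[, 1]
  list(y = transform(y), intercept = transform(rep(1, n)),
       transform = transform, delta = delta)
}

# Stage 2: lasso joint refit of stage-1 candidates, model chosen by BIC,
# then drop-one LOD in the joint OLS model.
gcim_stage2 <- function(y, M, cand, map, designs, threshold, genotypes) {
  if (length(cand) == 0) return(empty_peaks("GCIM"))
  n <- length(y)
  sel <- cand
  if (length(cand) >= 2) {
    fitnet <- glmnet::glmnet(M[, cand, drop = FALSE], y, alpha = 1,
                             standardize = TRUE)
    bic <- rep(Inf, length(fitnet$lambda))
    for (i in seq_along(fitnet$lambda)) {
      pred <- stats::predict(fitnet, M[, cand, drop = FALSE],
                             s = fitnet$lambda[i])
      rss <- sum((y - pred)^2)
      df <- fitnet$df[i]
      bic[i] <- n * log(rss / n) + (df + 1) * log(n)
    }
    co <- as.matrix(stats::coef(fitnet, s = fitnet$lambda[which.min(bic)]))[-1, 1]
    sel <- cand[co != 0]
    if (length(sel) == 0) sel <- cand[which.max(abs(co))]
  }
  X <- cbind(1, M[, sel, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  rss_null <- sum((y - mean(y))^2)
  peaks <- list()
  mk <- match(colnames(M)[sel], map$marker_id)
  for (jj in seq_along(sel)) {
    f0 <- stats::lm.fit(cbind(1, M[, sel[-jj], drop = FALSE]), y)
    rss0 <- sum(f0$residuals^2)
    lod <- max((n / 2) * log10(rss0 / max(rss_full, 1e-12)), 0)
    if (lod < threshold) next
    i <- mk[jj]
    eff <- marker_effects(y, genotypes[, map$marker_id[i]],
                          designs$population)
    peaks[[length(peaks) + 1]] <- data.frame(
      method = "GCIM", linkage_group = map$linkage_group[i],
      chrom = map$chrom[i], pos_cM = map$pos_cM[i],
      left_bp = map$pos_bp[i], right_bp = map$pos_bp[i], lod = lod,
      pve = 100 * max(rss0 - rss_full, 0) / rss_null,
      additive = eff$additive, dominance = eff$dominance,
      stringsAsFactors = FALSE
    )
  }
  if (length(peaks) == 0) empty_peaks("GCIM") else do.call(rbind, peaks)
}

# Single-marker additive/dominance effects for reporting.
marker_effects <- function(y, g_char, population) {
  g <- rep(NA_real_, length(g_char))
  g[g_char == "A"] <- 0
  g[g_char == "H"] <- 1
  g[g_char == "B"] <- 2
  keep <- !is.na(g)
  xa <- g[keep] - 1
  if (population == "F2") {
    xd <- as.numeric(g[keep] == 1)
    co <- stats::lm.fit(cbind(1, xa, xd), y[keep])$coefficients
    list(additive = unname(co[2]), dominance = unname(co[3]))
  } else {
    co <- stats::lm.fit(cbind(1, xa), y[keep])$coefficients
    list(additive = unname(co[2]), dominance = NA_real_)
  }
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Samples `n_sample_genes` genes without replacement, permutes each
#' sampled phenotype `n_perm` times, records the genome-wide maximum LOD
#' of every permutation, pools all `n_sample_genes * n_perm` maxima, and
#' returns their `(1 - alpha)` empirical percentile
#' (linear-interpolation definition). The default bookkeeping of 1,000
#' permutations for 100 sampled transcripts pools 100,000 null maxima.
#'
#' @param expression genes x lines matrix of normalized expression.
#' @inheritParams im_scan
#' @param method `"IM"` (vectorized fast path), `"ICIM"` or `"GCIM"`.
#' @param n_sample_genes genes sampled for the representative null.
#' @param n_perm permutations per gene; below 100 triggers a warning.
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed integer seed for sampling and permutation.
#' @return list with `threshold`, the pooled `maxima`, `n_pooled`,
#'   `alpha` and `method`.
#' @export
permutation_threshold <- function(expression, map = NULL, genotypes = NULL,
                                  population = c("F2", "RIL"),
                                  method = c("IM", "ICIM", "GCIM"),
                                  n_sample_genes = 100, n_perm = 1000,
                                  alpha = 0.05, seed = 1L, step_cM = 1,
                                  designs = NULL) {
  method <- match.arg(method)
  if (nrow(expression) < n_sample_genes) {
    stop("expression matrix has fewer than n_sample_genes genes",
         call. = FALSE)
  }
  if (n_perm < 100) {
    warning("n_perm < 100 gives an unstable percentile", call. = FALSE)
  }
  if (is.null(designs)) {
    designs <- scan_designs(map, genotypes, match.arg(population), step_cM)
  }
  set.seed(seed)
  genes <- sample(nrow(expression), n_sample_genes)
  maxima <- numeric(0)
  for (g in genes) {
    y <- as.numeric(expression[g, ])
    if (method == "IM") {
      Yp <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
      lods <- lod_profile_matrix(designs, Yp)
      maxima <- c(maxima, apply(lods, 2, max))
    } else {
      for (i in seq_len(n_perm)) {
        yp <- sample(y)
        res <- if (method == "ICIM") {
          icim_scan(yp, map, genotypes, designs = designs, threshold = Inf)
        } else {
          gcim_scan(yp, map, genotypes, designs = designs, threshold = Inf)
        }
        maxima <- c(maxima, max(res$profile$lod))
      }
    }
  }
  list(threshold = percentile(maxima, 100 * (1 - alpha)), maxima = maxima,
       n_pooled = length(maxima), alpha = alpha, method = method)
}
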