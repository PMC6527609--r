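#' Inputs of the NMD isoform-proportion model
#'
#' The model describes a gene with a common exon-skipping splice variant
#' on one ("minor") haplotype whose mis-spliced isoform carries a
#' premature termination codon and is degraded by nonsense-mediated decay
#' (NMD). Three steady-state observables constrain it:
#' \itemize{
#'   \item \code{k_hom}: in reference-haplotype homozygotes, surviving
#'     normal transcripts outnumber surviving mis-spliced ones by
#'     \code{k_hom} : 1 (c_n = k_hom * c_m);
#'   \item \code{k_het}: in heterozygotes, combined surviving normal
#'     transcripts outnumber combined surviving mis-spliced ones by
#'     \code{k_het} : 1 (c_n + a_n = k_het * (c_m + a_m));
#'   \item \code{r}: the reference haplotype's surviving total is
#'     \code{r} times the minor haplotype's (c_t = r * a_t).
#' }
#' The normal isoform is assumed NMD-immune (p_n = 1). Defaults
#' (100, 25, 3) encode mis-spliced fractions of ~1\% in reference
#' homozygotes, ~4\% in heterozygotes, and a 3:1 haplotype expression
#' ratio.
#'
#' @param k_hom,k_het,r Model constants (see above).
#' @return Object of class \code{rpe_nmd_inputs}.
#' @export
nmd_inputs <- function(k_hom = 100, k_het = 25, r = 3) {
  if (k_hom <= 1 || k_het <= 1) stop("k_hom and k_het must be > 1",
                                     call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  structure(list(k_hom = k_hom, k_het = k_het, r = r, p_n = 1),
            class = "rpe_nmd_inputs")
}

#' Solve the NMD isoform-proportion system
#'
#' Unknowns: n_c and n_a, the fractions of reference- and
#' minor-haplotype transcripts spliced normally, and p_m, the survival
#' probability of mis-spliced transcripts under NMD. With the
#' substitutions u = (1 - n_c) p_m and v = (1 - n_a) p_m the three
#' constraints become linear in (n_c, n_a, u, v) plus the bilinear
#' closure u (1 - n_a) = v (1 - n_c); elimination at runtime gives the
#' exact solution (no transcribed closed-form constants). A 1-D
#' root-finding reduction of the original nonlinear system cross-checks
#' the result.
#'
#' @param inputs An \code{\link{nmd_inputs}} object.
#' @param verify Run the root-finding cross-check (default TRUE).
#' @param tol Residual tolerance for feasibility/verification (1e-8).
#' @return Object of class \code{rpe_nmd_solution}: n_c, n_a, p_m, u, v,
#'   plus the inputs.
#' @export
solve_isoform_model <- function(inputs = nmd_inputs(), verify = TRUE,
                                tol = 1e-8) {
  stopifnot(inherits(inputs, "rpe_nmd_inputs"))
  kh <- inputs$k_hom; kt <- inputs$k_het; r <- inputs$r
  # eq1: n_c = kh * u          => n_c = kh u
  # eq3: n_c + u = r (n_a + v) => n_a = (kh + 1) u / r - v
  # eq2: n_c + n_a = kt (u + v) => v = alpha u,
  #      alpha = (kh + (kh + 1)/r - kt) / (kt + 1)
  alpha <- (kh + (kh + 1) / r - kt) / (kt + 1)
  denom <- (kh + 1) * (1 / r - alpha)
  if (abs(denom) < 1e-12 || abs(alpha) < 1e-12 || abs(1 - alpha) < 1e-12)
    stop("singular system: inputs admit no unique solution", call. = FALSE)
  # closure u(1 - n_a) = v(1 - n_c) => u = (1 - alpha) / denom
  u <- (1 - alpha) / denom
  v <- alpha * u
  n_c <- kh * u
  n_a <- (kh + 1) * u / r - v
  p_m <- u / (1 - n_c)
  sol <- c(n_c = n_c, n_a = n_a, p_m = p_m)
  if (any(!is.finite(sol)) || any(sol <= 0) || any(sol >= 1))
    stop("infeasible inputs: solution outside (0,1): ",
         paste(sprintf("%s=%.4g", names(sol), sol), collapse = ", "),
         call. = FALSE)
  resid <- c(n_c - kh * (1 - n_c) * p_m,
             n_c + n_a - kt * ((1 - n_c) * p_m + (1 - n_a) * p_m),
             n_c + (1 - n_c) * p_m - r * (n_a + (1 - n_a) * p_m))
  # residual scale grows with k_hom because (1 - n_c) cancels catastrophically
  if (max(abs(resid)) > 1e-10 * max(1, kh, kt, r))
    stop("internal error: constraint residuals exceed tolerance", call. = FALSE)
  if (verify) {
    chk <- .solve_isoform_rootfind(inputs)
    if (max(abs(chk - sol)) > tol)
      stop("cross-check failed: elimination and root-finding disagree",
           call. = FALSE)
  }
  structure(list(n_c = n_c, n_a = n_a, p_m = p_m, u = u, v = v,
                 inputs = inputs), class = "rpe_nmd_solution")
}

# Independent 1-D reduction: given p_m, eq1 and eq2 determine n_c and
# n_a; the eq3 residual is rooted over p_m in (0, 1).
.solve_isoform_rootfind <- function(inputs) {
  kh <- inputs$k_hom; kt <- inputs$k_het; r <- inputs$r
  f <- function(pm) {
    nc <- kh * pm / (1 + kh * pm)
    na <- 2 * kt * pm / (1 + kt * pm) - nc
    nc + (1 - nc) * pm - r * (na + (1 - na) * pm)
  }
  pm <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  nc <- kh * pm / (1 + kh * pm)
  na <- 2 * kt * pm / (1 + kt * pm) - nc
  c(n_c = nc, n_a = na, p_m = pm)
}

#' Observable fractions implied by an isoform-model solution
#'
#' @param sol An \code{rpe_nmd_solution}.
#' @return List: \code{cc_mis_pct} (surviving mis-spliced percentage in
#'   reference homozygotes; equals 100/(k_hom + 1) identically),
#'   \code{het_mis_pct} (same in heterozygotes; equals 100/(k_het + 1)),
#'   \code{hap_ratio} (surviving reference/minor total ratio; equals r),
#'   \code{nmd_degraded_pct} = 100 (1 - p_m).
#' @export
implied_fractions <- function(sol) {
  stopifnot(inherits(sol, "rpe_nmd_solution"))
  with(sol, list(
    cc_mis_pct = 100 * u / (n_c + u),
    het_mis_pct = 100 * (u + v) / (n_c + n_a + u + v),
    hap_ratio = (n_c + u) / (n_a + v),
    nmd_degraded_pct = 100 * (1 - p_m)))
}

#' Grid sensitivity scan of the isoform model
#'
#' Solves the model over a parameter grid; infeasible or singular cells
#' are flagged rather than raised.
#'
#' @param ranges Named list of numeric vectors over k_hom, k_het and/or r
#'   (parameters not listed stay at \code{base} values).
#' @param base An \code{\link{nmd_inputs}} giving the fixed values.
#' @return data.frame: k_hom, k_het, r, n_c, n_a, p_m, feasible.
#' @export
sensitivity_scan <- function(ranges, base = nmd_inputs()) {
  known <- c("k_hom", "k_het", "r")
  if (!length(ranges) || !all(names(ranges) %in% known))
    stop("ranges must be a non-empty named list over k_hom/k_het/r",
         call. = FALSE)
  grid_axes <- lapply(known, function(p)
    if (p %in% names(ranges)) ranges[[p]] else base[[p]])
  names(grid_axes) <- known
  grid <- expand.grid(grid_axes, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty grid", call. = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch(
      solve_isoform_model(nmd_inputs(grid$k_hom[i], grid$k_het[i],
                                     grid$r[i]), verify = FALSE),
      error = function(e) NULL)
    if (is.null(out))
      data.frame(n_c = NA_real_, n_a = NA_real_, p_m = NA_real_,
                 feasible = FALSE)
    else
      data.frame(n_c = out$n_c, n_a = out$n_a, p_m = out$p_m,
                 feasible = TRUE)
  })
  cbind(grid, do.call(rbind, res))
}
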