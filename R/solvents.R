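#' Built-in solvent descriptor table
#'
#' Returns the bundled table of 15 solvent descriptors for common solvents:
#' the Catalan SPP, SA and SB scales; the Kamlet-Taft alpha, beta and pi*
#' scales; four functions of the static dielectric constant eps (eps itself
#' and the Kirkwood/Onsager-type ratios (eps-1)/(eps+2), (eps-1)/(2eps+1),
#' (eps-1)/(eps+1)); three functions of the refractive index n (n^2,
#' (n^2-1)/(n^2+2), (n^2-1)/(2n^2+1)); and two user-definable slots (zero by
#' default) reserved for additional polarity scales. Values of the empirical
#' scales are typical literature values; the bulk-solvent functions are
#' computed from eps and n at 25 C.
#'
#' @param extra optional data frame of additional solvents to append: a
#'   `solvent` column plus the 15 descriptor columns of the built-in table
#'   (see [condition_names()]).
#' @return data frame with a `solvent` name column and 15 descriptor columns.
#' @export
solvent_table <- function(extra = NULL) {
  # solvent, SPP, SA, SB, alpha, beta, pi*, eps, nD
  raw <- read.csv(text = "solvent,SPP,SA,SB,alpha,beta,pi_star,eps,nD
water,0.962,1.062,0.025,1.17,0.47,1.09,78.36,1.333
methanol,0.857,0.605,0.545,0.98,0.66,0.60,32.66,1.328
ethanol,0.853,0.400,0.658,0.86,0.75,0.54,24.55,1.361
1-propanol,0.847,0.367,0.727,0.84,0.90,0.52,20.45,1.384
2-propanol,0.848,0.283,0.830,0.76,0.84,0.48,19.92,1.377
acetonitrile,0.895,0.044,0.286,0.19,0.40,0.75,35.94,1.344
acetone,0.881,0.000,0.475,0.08,0.43,0.71,20.56,1.359
dmso,1.000,0.072,0.647,0.00,0.76,1.00,46.45,1.478
dmf,0.954,0.031,0.613,0.00,0.69,0.88,36.71,1.430
thf,0.838,0.000,0.591,0.00,0.55,0.58,7.58,1.407
dichloromethane,0.876,0.040,0.178,0.13,0.10,0.82,8.93,1.424
chloroform,0.786,0.047,0.071,0.20,0.10,0.58,4.89,1.446
toluene,0.655,0.000,0.128,0.00,0.11,0.54,2.38,1.497
diethyl ether,0.694,0.000,0.562,0.00,0.47,0.27,4.20,1.352
", stringsAsFactors = FALSE)
  eps <- raw$eps; n2 <- raw$nD^2
  out <- data.frame(
    solvent = raw$solvent,
    SPP = raw$SPP, SA = raw$SA, SB = raw$SB,
    alpha = raw$alpha, beta = raw$beta, pi_star = raw$pi_star,
    eps = eps,
    f_eps_kirkwood = (eps - 1) / (2 * eps + 1),
    f_eps_onsager  = (eps - 1) / (eps + 2),
    f_eps_ratio    = (eps - 1) / (eps + 1),
    n_sq = n2,
    f_n_lorenz   = (n2 - 1) / (n2 + 2),
    f_n_kirkwood = (n2 - 1) / (2 * n2 + 1),
    user1 = 0, user2 = 0,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    miss <- setdiff(names(out), names(extra))
    if (length(miss))
      stop("extra solvent table is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    extra <- extra[, names(out)]
    if (anyNA(extra)) stop("extra solvent table contains missing values", call. = FALSE)
    out <- rbind(out, extra)
  }
  out
}

SOLVENT_DESC <- c("SPP", "SA", "SB", "alpha", "beta", "pi_star",
                  "eps", "f_eps_kirkwood", "f_eps_onsager", "f_eps_ratio",
                  "n_sq", "f_n_lorenz", "f_n_kirkwood", "user1", "user2")

#' Names of the condition descriptors
#'
#' The fixed 17-column condition block: 15 solvent descriptors, the inverse
#' absolute temperature `inv_T` (K^-1) and the organic-solvent molar ratio
#' `molar_ratio` (percent, 100 for a pure solvent).
#' @return character vector of length 17.
#' @export
condition_names <- function() c(SOLVENT_DESC, "inv_T", "molar_ratio")

#' Build the condition descriptor vector of one reaction
#'
#' @param solvent a solvent name registered in `table`, or a numeric vector of
#'   15 explicit solvent descriptor values (passed through unchanged).
#' @param temperature_K absolute temperature in Kelvin (> 0).
#' @param molar_ratio organic-solvent molar ratio in percent, in \[0, 100\];
#'   default 100 (pure solvent).
#' @param table solvent lookup table, default [solvent_table()].
#' @return named numeric vector of length 17.
#' @examples
#' condition_vector("water", 298.15, 100)
#' @export
condition_vector <- function(solvent, temperature_K, molar_ratio = 100,
                             table = solvent_table()) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be a positive temperature in Kelvin", call. = FALSE)
  if (molar_ratio < 0 || molar_ratio > 100)
    stop("molar_ratio must lie in [0, 100]", call. = FALSE)
  if (is.numeric(solvent)) {
    if (length(solvent) != 15L)
      stop("explicit solvent descriptors must have length 15", call. = FALSE)
    sv <- as.numeric(solvent)
  } else {
    hit <- match(tolower(solvent), tolower(table$solvent))
    if (is.na(hit))
      stop("unknown solvent ", sQuote(solvent), "; known solvents: ",
           paste(table$solvent, collapse = ", "), call. = FALSE)
    sv <- as.numeric(table[hit, SOLVENT_DESC])
  }
  out <- c(sv, 1 / temperature_K, molar_ratio)
  names(out) <- condition_names()
  out
}
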