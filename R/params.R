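#' Population (fixed) model parameters
#'
#' Parameters of the linearized glucose-insulin model that are held at
#' population values during individualization, except for the insulin
#' sensitivity `Si`, which is re-estimated daily. Units: rates in 1/min,
#' `Gb` in mg/dL, `Vg` in dL/kg, `Vi` in mL/kg, `BW` in kg, `Si` in
#' mL/U/min (it scales the insulin-action term of the glucose balance).
#'
#' @param Sg glucose effectiveness (1/min)
#' @param Gb basal glucose (mg/dL)
#' @param Vg glucose distribution volume (dL/kg)
#' @param BW body weight (kg)
#' @param p2 insulin action rate (1/min)
#' @param Vi insulin distribution volume (mL/kg)
#' @param Si insulin sensitivity (mL/U/min)
#' @param kc1,kc12,kc2,kcl rapid-insulin pharmacokinetic rates (1/min)
#' @return an object of class `population_parameters`
#' @export
population_parameters <- function(Sg, Gb, Vg, BW, p2, Vi, Si,
                                  kc1, kc12, kc2, kcl) {
  p <- list(Sg = Sg, Gb = Gb, Vg = Vg, BW = BW, p2 = p2, Vi = Vi, Si = Si,
            kc1 = kc1, kc12 = kc12, kc2 = kc2, kcl = kcl)
  rates <- c(Sg, p2, kc1, kc12, kc2, kcl)
  if (any(!is.finite(unlist(p))) || any(rates <= 0) || Si <= 0 ||
      Vg <= 0 || Vi <= 0)
    stop("population_parameters: all rates, volumes and Si must be positive")
  if (Gb <= 70 || Gb >= 200) stop("population_parameters: Gb outside (70, 200)")
  if (BW <= 30 || BW >= 200) stop("population_parameters: BW outside (30, 200)")
  structure(p, class = "population_parameters")
}

#' Long-acting insulin pharmacokinetic parameters
#'
#' Absorption model for the long-acting (basal) dose: a fraction
#' `precip_fraction` of the injected dose precipitates at the injection site
#' and redissolves at rate `ksp`; the soluble depot is absorbed into plasma
#' at rate `ka`; `F` is the overall bioavailability.
#'
#' @param F bioavailability, in (0, 1]
#' @param precip_fraction precipitating fraction of the dose, in [0, 1]
#' @param ksp precipitate-to-soluble dissolution rate (1/min)
#' @param ka soluble-depot absorption rate (1/min)
#' @return an object of class `basal_pk_parameters`
#' @export
basal_pk_parameters <- function(F, precip_fraction, ksp, ka) {
  if (!(F > 0 && F <= 1)) stop("basal_pk_parameters: F outside (0, 1]")
  if (precip_fraction < 0 || precip_fraction > 1)
    stop("basal_pk_parameters: precip_fraction outside [0, 1]")
  if (ksp <= 0 || ka <= 0) stop("basal_pk_parameters: rates must be positive")
  structure(list(F = F, precip_fraction = precip_fraction, ksp = ksp, ka = ka),
            class = "basal_pk_parameters")
}

#' Carbohydrate absorption parameters
#'
#' Two-compartment (stomach/gut) absorption with a direct stomach path:
#' `kq1` direct absorption, `kq12` stomach-to-gut transfer, `kq2` gut
#' absorption, `f` carbohydrate bioavailability.
#'
#' @param f carbohydrate bioavailability, in (0, 1.2]
#' @param kq1,kq2,kq12 absorption/transfer rates (1/min)
#' @return an object of class `meal_absorption_parameters`
#' @export
meal_absorption_parameters <- function(f, kq1, kq2, kq12) {
  if (!(f > 0 && f <= 1.2))
    stop("meal_absorption_parameters: f outside (0, 1.2]")
  if (any(c(kq1, kq2, kq12) <= 0))
    stop("meal_absorption_parameters: rates must be positive")
  structure(list(f = f, kq1 = kq1, kq2 = kq2, kq12 = kq12),
            class = "meal_absorption_parameters")
}

#' Default parameter set
#'
#' Reads the versioned population parameter configuration shipped with the
#' package (or a user-supplied file of the same layout) and returns typed
#' parameter groups.
#'
#' @param file YAML configuration file; defaults to the packaged one
#' @return list with elements `pop`, `basal`, `meal`, `rescue`
#' @export
default_parameters <- function(file = system.file("extdata",
                                                  "population_parameters.yaml",
                                                  package = "basalopt")) {
  cfg <- yaml::read_yaml(file)
  pp <- cfg$population
  list(
    pop = population_parameters(Sg = pp$Sg, Gb = pp$Gb, Vg = pp$Vg,
                                BW = pp$BW, p2 = pp$p2, Vi = pp$Vi,
                                Si = pp$Si, kc1 = pp$kc1, kc12 = pp$kc12,
                                kc2 = pp$kc2, kcl = pp$kcl),
    basal = basal_pk_parameters(F = cfg$basal_pk$F,
                                precip_fraction = cfg$basal_pk$precip_fraction,
                                ksp = cfg$basal_pk$ksp, ka = cfg$basal_pk$ka),
    meal = meal_absorption_parameters(f = cfg$meal$f, kq1 = cfg$meal$kq1,
                                      kq2 = cfg$meal$kq2, kq12 = cfg$meal$kq12),
    rescue = meal_absorption_parameters(f = cfg$rescue$f, kq1 = cfg$rescue$kq1,
                                        kq2 = cfg$rescue$kq2,
                                        kq12 = cfg$rescue$kq12)
  )
}
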