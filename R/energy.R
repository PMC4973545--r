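#' Noblet-Perez energy prediction equations
#'
#' Published linear equations predicting the digestible energy (DE) and
#' metabolizable energy (ME) content of pig feeds from proximate composition
#' (g/kg dry matter):
#'
#' \deqn{DE (MJ/kg) = (4168 - 9.1 Ash + 1.9 CP + 3.9 EE - 3.6 NDF) \times 4.18 / 1000}
#' \deqn{ME (MJ/kg) = DE \times (1.003 - 0.00021 CP)}
#'
#' The kcal-to-MJ factor is 4.18/1000 exactly. Composition tables are often
#' reported in % DM; multiply by 10 to obtain g/kg before calling, or use
#' [add_calculated_energy()] which handles the conversion.
#'
#' @param ash,cp,ee,ndf composition in g/kg DM (vectors recycle together).
#' @param de digestible energy in MJ/kg DM.
#' @return DE or ME in MJ/kg DM.
#' @examples
#' de <- noblet_perez_de(ash = 14.1, cp = 94.1, ee = 38.7, ndf = 120.2)
#' noblet_perez_me(de, cp = 94.1)
#' @export
noblet_perez_de <- function(ash, cp, ee, ndf) {
  if (any(c(ash, cp, ee, ndf) < 0)) abort("composition values must be >= 0.")
  (4168 - 9.1 * ash + 1.9 * cp + 3.9 * ee - 3.6 * ndf) * 4.18 / 1000
}

#' @rdname noblet_perez_de
#' @export
noblet_perez_me <- function(de, cp) {
  if (any(de < 0)) abort("DE must be >= 0.")
  if (any(cp < 14.29)) {
    warn("CP below 14.29 g/kg makes the ME multiplier exceed 1 (ME > DE).")
  }
  de * (1.003 - 0.00021 * cp)
}

#' Append calculated DE/ME to a composition table
#'
#' Evaluates the Noblet-Perez equations for each row of a composition data
#' frame and appends `de_c` and `me_c` columns (MJ/kg DM).
#'
#' @param data data frame with columns `ash`, `cp`, `ee`, `ndf`.
#' @param units `"percent_dm"` (the usual table units; converted x10 to
#'   g/kg) or `"g_per_kg"`.
#' @return `data` with `de_c` and `me_c` columns appended.
#' @export
add_calculated_energy <- function(data, units = c("percent_dm", "g_per_kg")) {
  units <- match.arg(units)
  k <- if (units == "percent_dm") 10 else 1
  dplyr::mutate(
    data,
    de_c = noblet_perez_de(k * .data$ash, k * .data$cp, k * .data$ee,
                           k * .data$ndf),
    me_c = noblet_perez_me(.data$de_c, k * .data$cp)
  )
}

#' Direct-method energy accounting from a balance trial
#'
#' Computes diet-level DE and ME from a digestion-metabolism balance record
#' (energy intake minus faecal, and minus faecal plus urinary, losses per kg
#' DM intake) and scales to the test ingredient by its inclusion rate, under
#' the assumption that the ingredient is the diet's only energy source.
#'
#' @param intake feed intake, kg DM.
#' @param ge_diet,ge_feces,ge_urine gross energy of diet, feces, urine (MJ).
#' @param inclusion ingredient inclusion fraction of the diet (default 0.968,
#'   a corn-only test-diet formulation).
#' @return A one-row tibble with diet- and ingredient-level `de` and `me`
#'   (MJ/kg DM).
#' @examples
#' direct_method(1, 16, 2, 0.5)
#' @export
direct_method <- function(intake, ge_diet, ge_feces, ge_urine,
                          inclusion = 0.968) {
  if (intake <= 0) abort("intake must be positive.")
  if (inclusion <= 0 || inclusion > 1) abort("inclusion must lie in (0, 1].")
  if (ge_feces + ge_urine > ge_diet) {
    abort("energy losses exceed gross energy intake.")
  }
  de_diet <- (ge_diet - ge_feces) / intake
  me_diet <- (ge_diet - ge_feces - ge_urine) / intake
  tibble::tibble(de_diet = de_diet, me_diet = me_diet,
                 de = de_diet / inclusion, me = me_diet / inclusion)
}
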