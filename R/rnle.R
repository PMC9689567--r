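#' Describe a lifting task for the Revised NIOSH Lifting Equation
#'
#' Builds a one-row tibble describing a manual lifting configuration in the
#' metric form used by the Revised NIOSH Lifting Equation (RNLE): the load
#' actually lifted and the seven task variables that drive the recommended
#' weight limit. Rows from several calls can be bound together and passed to
#' [rnle_assess()].
#'
#' @param sex `"male"` or `"female"` (selects the load constant).
#' @param age_band `"under45"` or `"over45"`.
#' @param load_kg Actual weight lifted (kg, > 0).
#' @param horizontal_cm Horizontal grip-to-ankle distance H (cm).
#' @param vertical_origin_cm Hand height at lift origin V (cm).
#' @param vertical_dest_cm Hand height at lift destination (cm).
#' @param asymmetry_deg Trunk asymmetry angle A (degrees, >= 0).
#' @param lifts_per_min Lifting frequency F (1/min, > 0).
#' @param duration_category Work duration: `"short"` (<= 1 h), `"medium"`
#'   (<= 2 h) or `"long"` (<= 8 h).
#' @param coupling Hand-to-object coupling quality: `"good"`, `"fair"` or
#'   `"poor"`.
#'
#' @return A one-row tibble with the task fields, ready for [rnle_assess()].
#' @examples
#' rnle_task(sex = "male", age_band = "under45", load_kg = 6.5,
#'           horizontal_cm = 40, vertical_origin_cm = 70,
#'           vertical_dest_cm = 120, lifts_per_min = 4)
#' @export
rnle_task <- function(sex, age_band, load_kg,
                      horizontal_cm, vertical_origin_cm, vertical_dest_cm,
                      asymmetry_deg = 0, lifts_per_min = 1,
                      duration_category = "short", coupling = "good") {
  sex <- check_enum(sex, c("male", "female"))
  age_band <- check_enum(age_band, c("under45", "over45"))
  duration_category <- check_enum(duration_category, c("short", "medium", "long"))
  coupling <- check_enum(coupling, c("good", "fair", "poor"))
  load_kg <- check_number(load_kg, min = 0, strict_min = TRUE)
  horizontal_cm <- check_number(horizontal_cm, min = 0)
  vertical_origin_cm <- check_number(vertical_origin_cm, min = 0)
  vertical_dest_cm <- check_number(vertical_dest_cm, min = 0)
  asymmetry_deg <- check_number(asymmetry_deg, min = 0)
  lifts_per_min <- check_number(lifts_per_min, min = 0, strict_min = TRUE)
  tibble::tibble(
    sex = sex, age_band = age_band, load_kg = load_kg,
    horizontal_cm = horizontal_cm,
    vertical_origin_cm = vertical_origin_cm,
    vertical_dest_cm = vertical_dest_cm,
    asymmetry_deg = asymmetry_deg, lifts_per_min = lifts_per_min,
    duration_category = duration_category, coupling = coupling
  )
}

#' Load constant of the Revised NIOSH Lifting Equation
#'
#' Sex- and age-specific load constant LC: 25/20 kg for males under/over 45
#' years, 20/15 kg for females under/over 45 years.
#'
#' @param sex `"male"` or `"female"`. Vectorised.
#' @param age_band `"under45"` or `"over45"`. Vectorised.
#' @return Load constant in kg.
#' @examples
#' rnle_load_constant("male", "under45")   # 25
#' rnle_load_constant("female", "over45")  # 15
#' @export
rnle_load_constant <- function(sex, age_band) {
  n <- max(length(sex), length(age_band))
  sex <- rep_len(sex, n); age_band <- rep_len(age_band, n)
  ok_sex <- sex %in% c("male", "female")
  ok_age <- age_band %in% c("under45", "over45")
  if (!all(ok_sex)) abort('`sex` must be "male" or "female".')
  if (!all(ok_age)) abort('`age_band` must be "under45" or "over45".')
  base <- ifelse(sex == "male", 25, 20)
  base - ifelse(age_band == "over45", 5, 0)
}

rnle_table_cache <- new.env(parent = emptyenv())

read_rnle_table <- function(file) {
  if (is.null(rnle_table_cache[[file]])) {
    path <- system.file("extdata", file, package = "liftrisk")
    if (!nzchar(path)) {
      abort(sprintf("lookup table '%s' not found in the installed package", file))
    }
    rnle_table_cache[[file]] <- readr::read_csv(
      path, comment = "#", show_col_types = FALSE, progress = FALSE
    )
  }
  rnle_table_cache[[file]]
}

#' RNLE frequency and coupling multiplier lookup tables
#'
#' The published frequency-multiplier (FM) and coupling-multiplier (GM) tables
#' shipped with the package as plain-text CSV (`inst/extdata`). FM is indexed
#' by lifting frequency, work-duration category and whether the hands start
#' below 75 cm; GM by coupling quality and the same height band.
#'
#' @return A tibble (long format, one multiplier value per row).
#' @export
rnle_fm_table <- function() read_rnle_table("rnle_fm_table.csv")

#' @rdname rnle_fm_table
#' @export
rnle_cm_table <- function() read_rnle_table("rnle_cm_table.csv")

lookup_fm <- function(lifts_per_min, duration_category, v_origin_cm) {
  tab <- rnle_fm_table()
  band <- ifelse(v_origin_cm < 75, "v_lt_75", "v_ge_75")
  freqs <- sort(unique(tab$lifts_per_min))
  vapply(seq_along(lifts_per_min), function(i) {
    f <- max(lifts_per_min[i], min(freqs))
    if (f > max(freqs)) return(0)
    # round up to the next tabulated frequency (conservative)
    f_tab <- freqs[which(freqs >= f - 1e-9)[1]]
    row <- tab[tab$lifts_per_min == f_tab &
                 tab$duration == duration_category[i] &
                 tab$v_band == band[i], ]
    row$fm[1]
  }, numeric(1))
}

lookup_gm <- function(coupling, v_origin_cm) {
  tab <- rnle_cm_table()
  band <- ifelse(v_origin_cm < 75, "v_lt_75", "v_ge_75")
  vapply(seq_along(coupling), function(i) {
    tab$gm[tab$coupling == coupling[i] & tab$v_band == band[i]][1]
  }, numeric(1))
}

#' RNLE task multipliers
#'
#' Computes the six dimensionless multipliers of the Revised NIOSH Lifting
#' Equation from a tibble of task descriptions (see [rnle_task()]):
#' horizontal `hm = 25/H` (H <= 25 cm gives 1), vertical
#' `vm = 1 - 0.003 |V - 75|`, displacement `dm = 0.82 + 4.5/D` (D below the
#' 25 cm floor gives 1), asymmetry `am = 1 - 0.0032 A`, and table lookups for
#' the frequency (`fm`) and coupling (`gm`) multipliers. All multipliers are
#' clamped to `[0, 1]`; geometry beyond the equation's validity envelope
#' (H > 63 cm, D > 175 cm, A > 135 degrees, V > 175 cm) yields 0.
#'
#' @param tasks A data frame of lifting tasks ([rnle_task()] rows).
#' @return `tasks` with columns `hm`, `vm`, `dm`, `am`, `fm`, `gm` appended.
#' @export
rnle_multipliers <- function(tasks) {
  stopifnot(is.data.frame(tasks))
  H <- tasks$horizontal_cm
  V0 <- tasks$vertical_origin_cm
  V1 <- tasks$vertical_dest_cm
  A <- tasks$asymmetry_deg
  D <- abs(V1 - V0)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  hm <- ifelse(H > 63, 0, clamp01(25 / pmax(H, 25)))
  vm <- ifelse(V0 > 175, 0, clamp01(1 - 0.003 * abs(V0 - 75)))
  dm <- ifelse(D > 175, 0, ifelse(D < 25, 1, clamp01(0.82 + 4.5 / D)))
  am <- ifelse(A > 135, 0, clamp01(1 - 0.0032 * A))
  fm <- lookup_fm(tasks$lifts_per_min, tasks$duration_category, V0)
  gm <- lookup_gm(tasks$coupling, V0)
  dplyr::mutate(tibble::as_tibble(tasks),
                hm = hm, vm = vm, dm = dm, am = am, fm = fm, gm = gm)
}

#' Recommended weight limit, lifting index and risk class
#'
#' Applies the full Revised NIOSH Lifting Equation to a tibble of lifting
#' tasks: `RWL = LC x HM x VM x DM x AM x FM x GM` and `LI = AWL / RWL`,
#' where AWL is the actual weight lifted (`load_kg`). Tasks with `LI < 1`
#' are classified `NO_RISK`; `LI >= 1` is classified `RISK` (the boundary
#' case is treated conservatively). A task whose multipliers drive the RWL
#' to zero has an undefined (infinite) lifting index and is flagged via
#' `li_defined = FALSE` while still being classified `RISK`.
#'
#' @param tasks A data frame of lifting tasks ([rnle_task()] rows).
#' @return A tibble with the task columns plus `lc_kg`, the six multipliers,
#'   `rwl_kg`, `li`, `li_defined`, `risk_class` and `table_version`.
#' @examples
#' rnle_task("male", "under45", load_kg = 6.5, horizontal_cm = 40,
#'           vertical_origin_cm = 70, vertical_dest_cm = 120,
#'           lifts_per_min = 4) |>
#'   rnle_assess()
#' @export
rnle_assess <- function(tasks) {
  out <- rnle_multipliers(tasks)
  out$lc_kg <- rnle_load_constant(out$sex, out$age_band)
  out$rwl_kg <- out$lc_kg * out$hm * out$vm * out$dm * out$am * out$fm * out$gm
  out$li <- ifelse(out$rwl_kg > 0, out$load_kg / out$rwl_kg, Inf)
  out$li_defined <- out$rwl_kg > 0
  out$risk_class <- classify_risk(out$li)
  out$table_version <- "RNLE-1991"
  dplyr::relocate(out, "lc_kg", .before = "hm")
}

#' Classify a lifting index into the binary NIOSH risk class
#'
#' @param li Lifting index values (>= 0; `Inf` allowed for degenerate tasks).
#' @return Character vector: `"NO_RISK"` when `li < 1`, `"RISK"` otherwise
#'   (`li == 1` is classified as `RISK`).
#' @examples
#' classify_risk(c(0.57, 1.64, 1))
#' @export
classify_risk <- function(li) {
  if (any(is.na(li)) || any(li < 0)) {
    abort("`li` must be non-negative and non-missing.")
  }
  ifelse(li < 1, "NO_RISK", "RISK")
}
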