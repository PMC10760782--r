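# Bundled case-study fixtures ---------------------------------------------

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tccmodel")
  if (!nzchar(p)) stop("fixture file not found: ", file, call. = FALSE)
  p
}

.named_matrix <- function(rows, colnames) {
  m <- do.call(rbind, lapply(rows, unlist))
  rownames(m) <- names(rows)
  colnames(m) <- colnames
  m
}

#' Load the Canadian residential-care case study
#'
#' Returns the bundled parameter set for the case study comparing a
#' sensor-based digital bladder diary (strategy `dht`) with conventional
#' continence care in Canadian nursing-home residents (mean age 86,
#' groups G2-G6, 2-month cycles, 5% annual discounting).
#'
#' The effect-side tables (initial distributions, group/care-stage/skin
#' transitions, mortality, event rates, utilities) plus the task-minute and
#' staffing tables come from the main fixture. The cost-side unit costs and
#' resource-use frequencies are only available as a clearly labelled
#' synthetic placeholder file (see [load_economics_synthetic()]): request it
#' with `economics = "synthetic"`, supply your own transcription via a file
#' path, or keep `economics = "none"` for effect-only analyses.
#'
#' @param strategy `"both"` (default) keeps both arms' tables in one set;
#'   `"conventional"` or `"dht"` restricts to one arm.
#' @param economics `"none"`, `"synthetic"`, or a path to a YAML file with
#'   the same layout as the synthetic fixture.
#' @return A validated [parameter_set()].
#' @examples
#' ps <- load_case_study()
#' ps$group_transition["G4", "G5"]    # 0.585
#' @export
load_case_study <- function(strategy = c("both", "conventional", "dht"),
                            economics = c("none", "synthetic")) {
  strategy <- match.arg(strategy)
  if (length(economics) == 1 && file.exists(economics)) {
    econ_file <- economics
  } else {
    economics <- match.arg(economics)
    econ_file <- if (economics == "synthetic") .fixture_path("economics_synthetic.yaml") else NULL
  }
  raw <- yaml::read_yaml(.fixture_path("case_study_main.yaml"))

  arms <- if (strategy == "both") strategies() else strategy
  groups <- unlist(raw$settings$included_groups)

  econ <- NULL
  if (!is.null(econ_file)) {
    econ <- load_economics_synthetic(econ_file)
    econ$task_minutes <- .named_matrix(raw$task_minutes, groups)
    econ$staff_per_task <- .named_matrix(raw$staff_per_task, groups)
    econ <- econ[c("synthetic", "wage_formal_per_min", "wage_informal_per_min",
                   "informal_share", "task_minutes", "staff_per_task",
                   "task_freq_per_day", "products", "hygiene_cost_per_application",
                   "disposal_tariff_per_kg", "event_costs",
                   "technology_cost_per_person_year", "shl5_treatment")]
  }

  parameter_set(
    settings = raw$settings,
    initial = lapply(raw$initial, unlist),
    group_transition = .named_matrix(raw$group_transition, groups),
    mortality = list(
      mean = .named_matrix(setNames(raw$mortality$mean, unlist(raw$mortality$bands)),
                           unlist(raw$mortality$classes)),
      lo = .named_matrix(setNames(raw$mortality$lo, unlist(raw$mortality$bands)),
                         unlist(raw$mortality$classes)),
      hi = .named_matrix(setNames(raw$mortality$hi, unlist(raw$mortality$bands)),
                         unlist(raw$mortality$classes))),
    cs_shift = raw$cs_shift,
    cs_transition = lapply(raw$cs_transition[arms], .named_matrix, colnames = care_stages()),
    shl_given_cs = lapply(raw$shl_given_cs[arms], .named_matrix, colnames = shl_levels()),
    event_rates = lapply(raw$event_rates[arms], unlist),
    utilities = list(group = unlist(raw$utilities$group),
                     d_cs = unlist(raw$utilities$d_cs),
                     d_shl = unlist(raw$utilities$d_shl),
                     d_event = unlist(raw$utilities$d_event)),
    economics = econ,
    meta = raw$meta)
}

#' Load the synthetic economics placeholder fixture
#'
#' Reads the cost-side block (wages, task frequencies, product prices and
#' weights, hygiene and disposal unit costs, event costs, technology price,
#' severe-skin-treatment costing). The bundled file is synthetic: plausible
#' values chosen to exercise the cost pathway, not a transcription of the
#' case study's cost inputs. The `synthetic: true` flag is carried through
#' so downstream reports can label cost results as illustrative.
#'
#' @param path YAML file; defaults to the bundled synthetic fixture.
#' @return A named list (the `economics` block of a [parameter_set()]),
#'   without the task-minute/staffing tables, which live in the main fixture.
#' @export
load_economics_synthetic <- function(path = .fixture_path("economics_synthetic.yaml")) {
  raw <- yaml::read_yaml(path)
  tasks_freq <- setdiff(task_labels(), "shl5_treatment")
  econ <- list(
    synthetic = isTRUE(raw$synthetic),
    wage_formal_per_min = raw$wage_formal_per_min,
    wage_informal_per_min = raw$wage_informal_per_min,
    informal_share = raw$informal_share,
    task_freq_per_day = lapply(raw$task_freq_per_day, function(arm)
      .named_matrix(arm[tasks_freq], care_stages())),
    products = list(
      price_per_piece = lapply(raw$products$price_per_piece, function(x)
        setNames(unlist(x), care_stages())),
      daily_count = lapply(raw$products$daily_count, function(x)
        setNames(unlist(x), care_stages())),
      dry_weight_kg = setNames(unlist(raw$products$dry_weight_kg), care_stages()),
      absorbency_ml = setNames(unlist(raw$products$absorbency_ml), care_stages())),
    hygiene_cost_per_application = raw$hygiene_cost_per_application,
    disposal_tariff_per_kg = raw$disposal_tariff_per_kg,
    event_costs = unlist(raw$event_costs),
    technology_cost_per_person_year = raw$technology_cost_per_person_year,
    shl5_treatment = raw$shl5_treatment)
  econ
}
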