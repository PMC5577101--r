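# Plate layout: the well -> (experiment, stimulus, treatment, role,
# replicate) mapping that drives all aggregation. Stored as a validated
# data.frame with a fixed schema.

.layout_cols <- c("well_id", "experiment_id", "stimulus", "stimulus_conc",
                  "stimulus_unit", "treatment", "treatment_conc",
                  "treatment_unit", "role", "replicate")
.layout_roles <- c("unstimulated-control", "stimulated-control", "test")

#' Validate a plate layout table
#'
#' Checks the schema (columns `well_id`, `experiment_id`, `stimulus`,
#' `stimulus_conc`, `stimulus_unit`, `treatment`, `treatment_conc`,
#' `treatment_unit`, `role`, `replicate`), uniqueness of wells and the
#' role vocabulary (`unstimulated-control`, `stimulated-control`, `test`).
#'
#' @param df a data.frame in the layout schema.
#' @param requireControls if TRUE (needed for percent inhibition), at least
#'   one stimulated and one unstimulated control row must be present.
#' @return the validated data.frame, with class `"PlateLayout"` prepended.
#' @export
plateLayout <- function(df, requireControls = FALSE) {
  missing_cols <- setdiff(.layout_cols, names(df))
  if (length(missing_cols))
    stopTyped("ecms_layout_schema", "plate map is missing columns: %s",
              paste(missing_cols, collapse = ", "))
  dup <- df$well_id[duplicated(df$well_id)]
  if (length(dup))
    stopTyped("ecms_layout_duplicate", "duplicated well_id: %s",
              paste(unique(dup), collapse = ", "))
  bad_role <- setdiff(unique(df$role), .layout_roles)
  if (length(bad_role))
    stopTyped("ecms_layout_role",
              "unknown role(s) %s in rows %s (expected %s)",
              paste(bad_role, collapse = ", "),
              paste(which(df$role %in% bad_role), collapse = ", "),
              paste(.layout_roles, collapse = ", "))
  if (requireControls) {
    if (!any(df$role == "stimulated-control") ||
        !any(df$role == "unstimulated-control"))
      stopTyped("ecms_layout_controls",
                "percent inhibition needs at least one stimulated-control and one unstimulated-control well")
  }
  df$stimulus_conc <- as.numeric(df$stimulus_conc)
  df$treatment_conc <- as.numeric(df$treatment_conc)
  df$replicate <- as.integer(df$replicate)
  class(df) <- unique(c("PlateLayout", class(df)))
  df
}

#' Read a plate map CSV
#'
#' @param path CSV file in the layout schema (see [plateLayout()]).
#' @param requireControls passed to [plateLayout()].
#' @return a validated `PlateLayout` data.frame.
#' @export
readPlateMap <- function(path, requireControls = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  plateLayout(df, requireControls = requireControls)
}

#' Parse a concentration string with units
#'
#' `"10 ng/mL"` becomes `list(value = 10, unit = "ng/mL")`.
#'
#' @param x a string like `"10 ng/mL"` or `"43 nM"`.
#' @return list with `value` (numeric) and `unit` (character).
#' @export
parseConcentration <- function(x) {
  m <- regmatches(x, regexec(
    "^\\s*([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*([^ ]+)\\s*$", x))[[1L]]
  if (length(m) != 3L)
    stopTyped("ecms_conc_parse", "cannot parse concentration '%s'", x)
  list(value = as.numeric(m[2L]), unit = m[3L])
}
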