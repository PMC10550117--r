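#' Per-event channel matrix for one tube
#'
#' An `EventTable` holds the list-mode data of one stained tube: a numeric
#' matrix with one row per acquired event and one column per detector, plus a
#' mapping from analysis roles (`fsc_a`, `fsc_h`, `ssc_a`, `viability`,
#' `cfse`, `luciferase`) to detector names. All downstream statistics operate
#' on the raw linear values stored here; no transform is applied at
#' construction.
#'
#' @param events numeric matrix, one row per event, one column per channel.
#'   All values must be finite. A 0-row matrix is a valid (empty) tube.
#' @param channel_names character vector of detector names, one per column.
#'   Defaults to `colnames(events)`.
#' @param channel_roles named character vector mapping roles to channel
#'   names, e.g. `c(fsc_a = "FSC-A", luciferase = "Luciferase-AF647-A")`.
#'   Every value must be present in `channel_names`. Roles other than the six
#'   known ones are rejected.
#' @param tube_id text label for the tube.
#'
#' @return an object of class `lucflow_event_table` with fields `events`,
#'   `channel_names`, `channel_roles`, `tube_id`.
#' @examples
#' m <- cbind(`FSC-A` = c(100, 200), `FSC-H` = c(95, 180))
#' et <- event_table(m, channel_roles = c(fsc_a = "FSC-A", fsc_h = "FSC-H"))
#' channel_values(et, "fsc_a")
#' @export
event_table <- function(events, channel_names = colnames(events),
                        channel_roles = character(), tube_id = "tube") {
  if (!is.matrix(events) || !is.numeric(events))
    lf_contract("`events` must be a numeric matrix")
  if (is.null(channel_names))
    lf_contract("channel names are required (set colnames or pass channel_names)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(events))
    lf_contract("one channel name per events column is required")
  if (anyDuplicated(channel_names))
    lf_contract("channel names must be unique")
  if (length(events) && !all(is.finite(events)))
    lf_contract("all event values must be finite")
  channel_roles <- validate_roles(channel_roles, channel_names)
  colnames(events) <- channel_names
  structure(
    list(events = events, channel_names = channel_names,
         channel_roles = channel_roles, tube_id = as.character(tube_id)[1]),
    class = "lucflow_event_table"
  )
}

known_roles <- c("fsc_a", "fsc_h", "ssc_a", "viability", "cfse", "luciferase")

validate_roles <- function(channel_roles, channel_names) {
  if (length(channel_roles) == 0) return(stats::setNames(character(), character()))
  channel_roles <- unlist(channel_roles)
  rn <- names(channel_roles)
  if (is.null(rn) || any(!nzchar(rn)))
    lf_contract("channel_roles must be a named vector role -> channel name")
  bad <- setdiff(rn, known_roles)
  if (length(bad))
    lf_contract(sprintf("unknown role(s): %s (known: %s)",
                        paste(bad, collapse = ", "),
                        paste(known_roles, collapse = ", ")))
  missing <- setdiff(unname(channel_roles), channel_names)
  if (length(missing))
    lf_contract(sprintf("role channel(s) not present in table: %s",
                        paste(missing, collapse = ", ")))
  channel_roles
}

#' @export
print.lucflow_event_table <- function(x, ...) {
  cat(sprintf("<EventTable '%s': %d events x %d channels>\n",
              x$tube_id, nrow(x$events), ncol(x$events)))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (length(x$channel_roles))
    cat("roles:   ",
        paste(sprintf("%s=%s", names(x$channel_roles), x$channel_roles),
              collapse = ", "), "\n")
  invisible(x)
}

#' Extract the values of one analysis role
#'
#' @param table an [event_table()].
#' @param role one of `fsc_a`, `fsc_h`, `ssc_a`, `viability`, `cfse`,
#'   `luciferase`.
#' @return numeric vector, one value per event.
#' @export
channel_values <- function(table, role) {
  stopifnot(inherits(table, "lucflow_event_table"))
  role <- match.arg(role, known_roles)
  if (!role %in% names(table$channel_roles))
    lf_contract(sprintf("role '%s' is not assigned in this table", role))
  table$events[, table$channel_roles[[role]]]
}

# internal: assert that the roles a gate/statistic needs are assigned
require_roles <- function(table, roles) {
  missing <- setdiff(roles, names(table$channel_roles))
  if (length(missing))
    lf_contract(sprintf("tube '%s' is missing required channel role(s): %s",
                        table$tube_id, paste(missing, collapse = ", ")))
  invisible(TRUE)
}

n_events <- function(table) nrow(table$events)
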