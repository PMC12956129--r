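#' Create a solvent-exchange step
#'
#' A step is the atomic unit of a routine: soak the tissue in ethanol at
#' `concentration` for `duration_min` minutes. Concentrations are ethanol
#' volume fractions in `[0, 1]`; protocol files store them as percent to match
#' the device display.
#'
#' @param concentration Ethanol volume fraction, in `[0, 1]`.
#' @param duration_min Soak duration in minutes, finite and `> 0`.
#' @return A list of class `"tp_step"` with fields `concentration` and
#'   `duration_min`.
#' @examples
#' exchange_step(0.70, 30)
#' @export
exchange_step <- function(concentration, duration_min) {
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            is.numeric(duration_min), length(duration_min) == 1L)
  if (!is.finite(concentration) || concentration < 0 || concentration > 1) {
    stop("step concentration must be an ethanol fraction in [0, 1], got ",
         concentration, call. = FALSE)
  }
  if (!is.finite(duration_min) || duration_min <= 0) {
    stop("step duration must be a positive, finite number of minutes, got ",
         duration_min, call. = FALSE)
  }
  structure(list(concentration = as.numeric(concentration),
                 duration_min = as.numeric(duration_min)),
            class = "tp_step")
}

#' Create a named solvent-exchange routine
#'
#' @param id Positive integer routine identifier (unique within a store).
#' @param name Free-text routine name.
#' @param steps A list of [exchange_step()] objects, or a two-column data frame with
#'   columns `concentration` (fraction) and `duration_min`.
#' @return A list of class `"tp_routine"` with fields `id`, `name` and
#'   `steps` (a data frame with columns `concentration`, `duration_min`).
#' @examples
#' routine(1, "quick dehydration", list(exchange_step(0.5, 30), exchange_step(0.7, 30)))
#' @export
routine <- function(id, name, steps = list()) {
  stopifnot(length(id) == 1L, is.numeric(id))
  if (!is.finite(id) || id <= 0 || id != round(id)) {
    stop("routine id must be a positive integer, got ", id, call. = FALSE)
  }
  stopifnot(is.character(name), length(name) == 1L)
  if (is.data.frame(steps)) {
    stopifnot(all(c("concentration", "duration_min") %in% names(steps)))
    steps <- data.frame(concentration = as.numeric(steps$concentration),
                        duration_min = as.numeric(steps$duration_min))
  } else {
    stopifnot(is.list(steps))
    steps <- data.frame(
      concentration = vapply(steps, function(s) s$concentration, numeric(1)),
      duration_min = vapply(steps, function(s) s$duration_min, numeric(1))
    )
  }
  structure(list(id = as.integer(id), name = name, steps = steps),
            class = "tp_routine")
}

#' @export
print.tp_routine <- function(x, ...) {
  cat(sprintf("<routine %d: \"%s\", %d step%s, %g min total soak>\n",
              x$id, x$name, nrow(x$steps), if (nrow(x$steps) == 1) "" else "s",
              sum(x$steps$duration_min)))
  if (nrow(x$steps) > 0) {
    print(data.frame(step = seq_len(nrow(x$steps)),
                     concentration_pct = x$steps$concentration * 100,
                     duration_min = x$steps$duration_min),
          row.names = FALSE)
  }
  invisible(x)
}

#' Create a protocol store
#'
#' A protocol store mirrors the device's on-card JSON file: a collection of
#' named routines keyed by id, plus a format version. See
#' [read_protocol_store()] / [write_protocol_store()] for the file format.
#'
#' @param routines A list of [routine()] objects with distinct ids.
#' @param format_version Integer schema version (currently 1).
#' @return A list of class `"tp_protocol_store"`.
#' @export
protocol_store <- function(routines = list(), format_version = 1L) {
  stopifnot(is.list(routines))
  ids <- vapply(routines, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) {
    stop("routine ids must be unique within a store; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  routines <- routines[order(ids)]
  names(routines) <- vapply(routines, function(r) as.character(r$id),
                            character(1))
  structure(list(format_version = as.integer(format_version),
                 routines = routines),
            class = "tp_protocol_store")
}

#' @export
print.tp_protocol_store <- function(x, ...) {
  cat(sprintf("<protocol store: %d routine%s, format v%d>\n",
              length(x$routines), if (length(x$routines) == 1) "" else "s",
              x$format_version))
  for (r in x$routines) {
    cat(sprintf("  [%d] %s (%d steps)\n", r$id, r$name, nrow(r$steps)))
  }
  invisible(x)
}

#' Fetch one routine from a store by id
#'
#' @param store A [protocol_store()].
#' @param id Routine id.
#' @return The matching `"tp_routine"`.
#' @export
get_routine <- function(store, id) {
  stopifnot(inherits(store, "tp_protocol_store"))
  r <- store$routines[[as.character(as.integer(id))]]
  if (is.null(r)) {
    stop("no routine with id ", id, " in store (available: ",
         paste(names(store$routines), collapse = ", "), ")", call. = FALSE)
  }
  r
}

# Schema of the on-disk document:
# {"format_version": 1,
#  "routines": [{"id": 1, "name": "...",
#                "steps": [{"concentration_pct": 50, "duration_min": 30}]}]}
# Concentrations are stored as percent (device display convention); unknown
# keys are ignored on read and never emitted on write.

#' Read a protocol store from its JSON document
#'
#' Parses the device's protocol file. Malformed JSON raises a parse error with
#' the parser's position information; documents that parse but violate the
#' schema raise a validation error naming the offending routine or step.
#'
#' @param input Path to a JSON file, or a literal JSON string.
#' @return A `"tp_protocol_store"`.
#' @seealso [write_protocol_store()]
#' @export
read_protocol_store <- function(input) {
  stopifnot(is.character(input), length(input) == 1L)
  doc <- tryCatch(
    jsonlite::fromJSON(input, simplifyVector = FALSE),
    error = function(e) {
      stop("protocol store parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!is.list(doc)) {
    stop("protocol store must be a JSON object at top level", call. = FALSE)
  }
  fv <- doc[["format_version"]]
  if (is.null(fv) || !is.numeric(fv)) {
    stop("protocol store is missing a numeric \"format_version\"",
         call. = FALSE)
  }
  rts <- doc[["routines"]]
  if (is.null(rts)) rts <- list()
  if (!is.list(rts)) {
    stop("\"routines\" must be a JSON array", call. = FALSE)
  }
  routines <- lapply(seq_along(rts), function(i) {
    r <- rts[[i]]
    where <- sprintf("routine %d of %d", i, length(rts))
    if (!is.list(r) || is.null(r[["id"]]) || !is.numeric(r[["id"]])) {
      stop("invalid ", where, ": missing numeric \"id\"", call. = FALSE)
    }
    nm <- r[["name"]]
    if (is.null(nm)) nm <- paste("routine", r[["id"]])
    steps <- r[["steps"]]
    if (is.null(steps)) steps <- list()
    step_list <- lapply(seq_along(steps), function(j) {
      s <- steps[[j]]
      if (!is.list(s) || !is.numeric(s[["concentration_pct"]]) ||
          !is.numeric(s[["duration_min"]])) {
        stop("invalid step ", j, " in routine id ", r[["id"]],
             ": need numeric \"concentration_pct\" and \"duration_min\"",
             call. = FALSE)
      }
      tryCatch(exchange_step(s[["concentration_pct"]] / 100, s[["duration_min"]]),
               error = function(e) {
                 stop("invalid step ", j, " in routine id ", r[["id"]], ": ",
                      conditionMessage(e), call. = FALSE)
               })
    })
    routine(r[["id"]], as.character(nm), step_list)
  })
  protocol_store(routines, format_version = fv)
}

#' Write a protocol store to its JSON document
#'
#' Output is deterministic (stable key order, fixed formatting), so files
#' written from equal stores are byte-identical and diff cleanly, and
#' [read_protocol_store()] inverts it exactly.
#'
#' @param store A `"tp_protocol_store"`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON document as a single string (invisibly when `path` is
#'   given).
#' @export
write_protocol_store <- function(store, path = NULL) {
  stopifnot(inherits(store, "tp_protocol_store"))
  doc <- list(
    format_version = jsonlite::unbox(as.integer(store$format_version)),
    routines = lapply(unname(store$routines), function(r) {
      list(
        id = jsonlite::unbox(r$id),
        name = jsonlite::unbox(r$name),
        steps = lapply(seq_len(nrow(r$steps)), function(i) {
          list(
            concentration_pct = jsonlite::unbox(
              round(r$steps$concentration[i] * 100, 10)),
            duration_min = jsonlite::unbox(r$steps$duration_min[i])
          )
        })
      )
    })
  )
  txt <- as.character(jsonlite::toJSON(doc, pretty = TRUE, digits = NA))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Built-in propidium-iodide staining routines
#'
#' The two graded ethanol series used by the reference PI staining workflow:
#' routine 1 is the dehydration/rehydration series run after fixation (14
#' steps: 50, 70, 85, 95, 100, 100, 95, 85, 70, 50, 30, 15, 0, 0 % ethanol),
#' and routine 2 is the post-stain re-dehydration series (10 steps: 0, 0, 15,
#' 30, 50, 70, 85, 95, 100, 100 % ethanol, ending with the tissue in absolute
#' ethanol). Every step soaks for 30 minutes; together the two routines cover
#' 24 sequential solvent exchanges.
#'
#' @return A `"tp_protocol_store"` holding the two routines.
#' @examples
#' builtin_pi_routines()
#' @export
builtin_pi_routines <- function() {
  mk <- function(pcts) lapply(pcts / 100, exchange_step, duration_min = 30)
  protocol_store(list(
    routine(1L, "PI dehydration/rehydration series",
            mk(c(50, 70, 85, 95, 100, 100, 95, 85, 70, 50, 30, 15, 0, 0))),
    routine(2L, "PI post-stain re-dehydration series",
            mk(c(0, 0, 15, 30, 50, 70, 85, 95, 100, 100)))
  ))
}

#' Validate a routine against a device configuration
#'
#' Validation is total: any parseable routine yields a report, never an error.
#' Violations checked: empty routine, non-positive or non-finite durations,
#' and step concentrations outside the range achievable from the configured
#' stock solutions.
#'
#' @param routine A `"tp_routine"`.
#' @param config A [device_config()]; its stock set defines the achievable
#'   concentration range.
#' @return A data frame of class `"tp_validation_report"` with columns
#'   `step` (index, `NA` for routine-level violations), `field` and `message`;
#'   zero rows means the routine is valid.
#' @export
validate_routine <- function(routine, config) {
  stopifnot(inherits(routine, "tp_routine"), inherits(config, "tp_device_config"))
  viol <- list()
  add <- function(step, field, message) {
    viol[[length(viol) + 1L]] <<- data.frame(step = step, field = field,
                                             message = message)
  }
  n <- nrow(routine$steps)
  if (n == 0L) {
    add(NA_integer_, "steps", "empty routine: an executable routine needs at least one step")
  }
  cmin <- min(config$stocks$concentration)
  cmax <- max(config$stocks$concentration)
  for (i in seq_len(n)) {
    ci <- routine$steps$concentration[i]
    di <- routine$steps$duration_min[i]
    if (!is.finite(ci) || ci < cmin - 1e-9 || ci > cmax + 1e-9) {
      add(i, "concentration",
          sprintf("unreachable concentration %.4g: stocks span [%.4g, %.4g]",
                  ci, cmin, cmax))
    }
    if (!is.finite(di) || di <= 0) {
      add(i, "duration_min", sprintf("non-positive duration %.4g min", di))
    }
  }
  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(step = integer(), field = character(), message = character())
  class(report) <- c("tp_validation_report", "data.frame")
  report
}

#' @export
print.tp_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("routine valid: 0 violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Test whether a validation report is clean
#'
#' @param report A `"tp_validation_report"` from [validate_routine()].
#' @return `TRUE` when the report lists no violations.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "tp_validation_report"))
  nrow(report) == 0L
}
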