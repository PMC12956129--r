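#' Solve the stock-blending problem for one step
#'
#' Computes how much to draw from each stock reservoir so that the premix
#' container holds `total_volume` mL at the target ethanol concentration.
#' When the target matches a stock concentration exactly (within 1e-9) the
#' plan uses only that stock; otherwise it uses exactly the two adjacent
#' stocks bracketing the target, with
#' `v_hi = V * (c_t - c_lo) / (c_hi - c_lo)` and `v_lo = V - v_hi`.
#' Mixing is treated as volume-additive (nominal series labels; the device
#' carries no densitometry).
#'
#' Using the bracketing pair — water + 70% for targets below 70%, 70% + 100%
#' above — minimizes consumption of absolute ethanol. Alternative strategies
#' can be plugged in via `strategy`.
#'
#' @param target_concentration Ethanol fraction in `[min stock, max stock]`.
#' @param total_volume Total premix volume in mL, > 0.
#' @param stocks Stock set from [stock_set()] (sorted ascending, distinct).
#' @param calibration Optional [pump_calibration()]; when given, per-stock
#'   pump run times are filled in (unrounded), otherwise they are `NA`.
#' @param strategy Blending strategy; only `"adjacent"` is built in.
#' @return A list of class `"tp_dose_plan"`: `doses` (data frame with columns
#'   `name`, `concentration`, `pump_id`, `volume_ml`, `pump_time_s`),
#'   `total_volume`, `target_concentration`, `achieved_concentration`.
#' @examples
#' blend(0.85, 250, default_stocks())  # 125 mL of each ethanol stock
#' @export
blend <- function(target_concentration, total_volume, stocks,
                  calibration = NULL, strategy = "adjacent") {
  stopifnot(is.numeric(target_concentration), length(target_concentration) == 1L,
            is.numeric(total_volume), length(total_volume) == 1L,
            identical(strategy, "adjacent"))
  if (!is.data.frame(stocks) || nrow(stocks) == 0L) {
    stop("configuration error: empty stock set", call. = FALSE)
  }
  if (is.unsorted(stocks$concentration, strictly = TRUE)) {
    stop("stocks must be sorted by strictly ascending concentration",
         call. = FALSE)
  }
  if (!is.finite(total_volume) || total_volume <= 0) {
    stop("total volume must be positive, got ", total_volume, call. = FALSE)
  }
  ct <- target_concentration
  conc <- stocks$concentration
  tol <- 1e-9
  if (!is.finite(ct) || ct < min(conc) - tol || ct > max(conc) + tol) {
    stop(sprintf(
      "unreachable concentration %.4g: configured stocks span [%.4g, %.4g]",
      ct, min(conc), max(conc)), call. = FALSE)
  }
  volumes <- numeric(nrow(stocks))
  exact <- which(abs(conc - ct) <= tol)
  if (length(exact)) {
    volumes[exact[1L]] <- total_volume
  } else {
    i <- findInterval(ct, conc)   # conc[i] < ct < conc[i + 1]
    c_lo <- conc[i]; c_hi <- conc[i + 1L]
    v_hi <- total_volume * (ct - c_lo) / (c_hi - c_lo)
    volumes[i + 1L] <- v_hi
    volumes[i] <- total_volume - v_hi
  }
  doses <- data.frame(name = stocks$name,
                      concentration = conc,
                      pump_id = stocks$pump_id,
                      volume_ml = volumes,
                      pump_time_s = if (is.null(calibration)) NA_real_ else
                        pump_time_for_volume(volumes, calibration))
  structure(list(doses = doses,
                 total_volume = total_volume,
                 target_concentration = ct,
                 achieved_concentration = sum(conc * volumes) / total_volume),
            class = "tp_dose_plan")
}

#' @export
print.tp_dose_plan <- function(x, ...) {
  cat(sprintf("<dose plan: %g mL at %.4g%% ethanol (achieved %.4g%%)>\n",
              x$total_volume, x$target_concentration * 100,
              x$achieved_concentration * 100))
  used <- x$doses[x$doses$volume_ml > 0, , drop = FALSE]
  print(data.frame(stock = used$name,
                   volume_ml = round(used$volume_ml, 3),
                   pump_time_s = round(used$pump_time_s, 2)),
        row.names = FALSE)
  invisible(x)
}
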