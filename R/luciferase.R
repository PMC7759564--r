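# Dual-luciferase normalization and group comparison.
#
# Per well, the Firefly/Renilla ratio F/R cancels transfection
# efficiency; the mean control ratio ("average1") is then used as the
# unit so the control group is normalized to 1 by construction, and the
# two normalized groups are compared with a two-sample t-test.

#' Construct a luciferase plate from raw well readings
#'
#' @param control,experimental Data.frames (or lists) with columns `F`
#'   and `R`, one row per well; at least 2 wells per group and all
#'   luminescence values positive.
#' @return An object of class `luciferase_plate`.
#' @export
luciferase_plate <- function(control, experimental) {
  control <- as.data.frame(control)
  experimental <- as.data.frame(experimental)
  for (g in list(control, experimental)) {
    if (!all(c("F", "R") %in% names(g)) || nrow(g) < 2L) {
      stop("each group needs columns F and R and at least 2 wells",
           call. = FALSE)
    }
    if (any(g$F <= 0) || any(g$R <= 0)) {
      stop("luminescence values must be positive", call. = FALSE)
    }
  }
  structure(list(control = control, experimental = experimental,
                 labels = c(control = "control",
                            experimental = "experimental")),
            class = "luciferase_plate")
}

#' Read a luciferase plate from CSV
#'
#' Expected columns: `group` (`control`/`experimental`), `F`, `R`.
#'
#' @param path CSV file.
#' @return A [luciferase_plate()].
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "F", "R") %in% names(df)))
  luciferase_plate(df[df$group == "control", c("F", "R")],
                   df[df$group == "experimental", c("F", "R")])
}

#' Write a luciferase plate to CSV
#'
#' @param plate A [luciferase_plate()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  df <- rbind(data.frame(group = "control", plate$control),
              data.frame(group = "experimental", plate$experimental))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative luciferase activity and group comparison
#'
#' Computes per-well ratios `r = F/R`, normalizes both groups by the
#' mean control ratio (`average1`), and compares the normalized groups
#' with a two-sided two-sample t-test (equal-variance by default; set
#' `var_equal = FALSE` for the Welch variant). Significance annotation:
#' `"**"` iff `p <= 0.01`, `"*"` iff `0.01 < p <= 0.05`, otherwise
#' `"ns"`.
#'
#' @param plate A [luciferase_plate()].
#' @param var_equal Assume equal variances (default `TRUE`).
#' @return List with `control_norm`, `experimental_norm`, `means`
#'   (named numeric), `p_value`, and `significance`.
#' @export
luciferase_relative_activity <- function(plate, var_equal = TRUE) {
  stopifnot(inherits(plate, "luciferase_plate"))
  if (any(plate$control$R <= 0) || any(plate$experimental$R <= 0)) {
    stop("non-positive Renilla reading: ratio undefined", call. = FALSE)
  }
  r_ctrl <- plate$control$F / plate$control$R
  r_exp <- plate$experimental$F / plate$experimental$R
  average1 <- mean(r_ctrl)
  ctrl_norm <- r_ctrl / average1
  exp_norm <- r_exp / average1
  if (stats::sd(ctrl_norm) == 0 && stats::sd(exp_norm) == 0) {
    # degenerate: no within-group variance; identical means mean p = 1
    p <- if (isTRUE(all.equal(mean(ctrl_norm), mean(exp_norm)))) 1 else 0
  } else {
    p <- stats::t.test(ctrl_norm, exp_norm, var.equal = var_equal)$p.value
  }
  list(control_norm = ctrl_norm,
       experimental_norm = exp_norm,
       means = c(control = mean(ctrl_norm), experimental = mean(exp_norm)),
       average1 = average1,
       p_value = p,
       significance = if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns")
}
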