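# Derived cardiovascular risk quantities used as profile indicators:
# the Framingham point score (women's total-cholesterol point system) and
# mean arterial pressure.

#' Load the women's Framingham point table
#'
#' Reads the versioned JSON point table shipped with the package (or a
#' user-supplied file with the same schema). The table defines left-closed
#' scoring categories for age, total cholesterol, HDL-C and blood pressure,
#' plus smoking and diabetes points.
#'
#' @param path path to a point-table JSON file; defaults to the packaged
#'   women's table.
#' @return a list of class `"fps_table"`.
#' @export
fps_point_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "framingham_points_women.json",
                        package = "cvlpa", mustWork = TRUE)
  }
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("age", "total_cholesterol", "hdl", "blood_pressure")) {
    if (is.null(tab[[nm]])) stop("point table missing component: ", nm)
  }
  structure(tab, class = "fps_table")
}

# Category index for a left-closed partition; errors outside the domain
# rather than clamping.
.fps_category <- function(x, cuts, domain, what) {
  bad <- !is.na(x) & (x < domain[1] | x >= domain[2])
  if (any(bad)) {
    stop(sprintf("%s value %s outside the scored range [%s, %s)",
                 what, format(x[bad][1]), domain[1], domain[2]))
  }
  findInterval(x, cuts) + 1L
}

#' Mean arterial pressure
#'
#' One-third pulse-pressure formula: `dbp + (sbp - dbp) / 3`.
#'
#' @param sbp systolic blood pressure, mm Hg.
#' @param dbp diastolic blood pressure, mm Hg.
#' @return mean arterial pressure, mm Hg.
#' @examples
#' mean_arterial_pressure(120, 80)
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0, na.rm = TRUE)) stop("dbp must be positive")
  if (any(sbp < dbp, na.rm = TRUE)) stop("sbp must be >= dbp")
  dbp + (sbp - dbp) / 3
}

#' Framingham point score (women)
#'
#' Sums the category points for age, total cholesterol, HDL-C, blood
#' pressure, smoking and diabetes according to the women's
#' total-cholesterol point system. Blood pressure is scored on the joint
#' systolic-by-diastolic grid; when the two pressures fall in discordant
#' categories the higher-risk category governs. Inputs outside the scored
#' ranges raise an error; nothing is clamped.
#'
#' @param age years.
#' @param total_cholesterol mg/dL.
#' @param hdl mg/dL.
#' @param sbp,dbp mm Hg.
#' @param smoker logical or 0/1.
#' @param diabetic logical or 0/1; defaults to absent.
#' @param table an `fps_table`, see [fps_point_table()].
#' @return integer vector of point scores.
#' @examples
#' framingham_points(53, 208, 72, 117, 75, smoker = FALSE)
#' @export
framingham_points <- function(age, total_cholesterol, hdl, sbp, dbp,
                              smoker, diabetic = FALSE,
                              table = fps_point_table()) {
  stopifnot(inherits(table, "fps_table"))
  n <- length(age)
  args <- list(total_cholesterol, hdl, sbp, dbp, smoker)
  if (any(vapply(args, length, 1L) != n)) {
    stop("all inputs must have the same length")
  }
  if (length(diabetic) == 1L) diabetic <- rep(diabetic, n)
  if (any(total_cholesterol <= 0 | hdl <= 0 | sbp <= 0 | dbp <= 0,
          na.rm = TRUE)) {
    stop("cholesterol and pressures must be positive")
  }
  if (any(sbp < dbp, na.rm = TRUE)) stop("sbp must be >= dbp")

  a <- table$age
  tc <- table$total_cholesterol
  h <- table$hdl
  bp <- table$blood_pressure

  pts <- a$points[.fps_category(age, a$cuts, a$domain, "age")] +
    tc$points[.fps_category(total_cholesterol, tc$cuts, tc$domain,
                            "total cholesterol")] +
    h$points[.fps_category(hdl, h$cuts, h$domain, "HDL-C")]

  cat_s <- .fps_category(sbp, bp$sbp_cuts, bp$sbp_domain, "systolic pressure")
  cat_d <- .fps_category(dbp, bp$dbp_cuts, bp$dbp_domain, "diastolic pressure")
  pts <- pts + bp$points[pmax(cat_s, cat_d)]

  pts <- pts + as.integer(smoker) * table$smoker_points +
    as.integer(diabetic) * table$diabetes_points
  as.integer(pts)
}

#' Attainable range of the point score
#'
#' Brute-force enumeration over the finite category grid: the sum of the
#' per-factor minimum and maximum points.
#'
#' @param table an `fps_table`.
#' @return integer vector `c(min, max)`.
#' @export
fps_attainable_range <- function(table = fps_point_table()) {
  parts <- list(table$age$points, table$total_cholesterol$points,
                table$hdl$points, table$blood_pressure$points,
                c(0L, table$smoker_points), c(0L, table$diabetes_points))
  c(sum(vapply(parts, min, 1)), sum(vapply(parts, max, 1)))
}

#' Vectorized Framingham scoring over a cohort table
#'
#' Applies [framingham_points()] row-wise to the columns `age`,
#' `total_cholesterol`, `hdl`, `sbp`, `dbp`, `smoker` (and `diabetic` if
#' present) of a cohort data frame.
#'
#' @param cohort a data frame with the required columns.
#' @param table an `fps_table`.
#' @return integer vector, one score per row.
#' @export
fps_column <- function(cohort, table = fps_point_table()) {
  need <- c("age", "total_cholesterol", "hdl", "sbp", "dbp", "smoker")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(cohort) == 0L) return(integer(0))
  for (cn in need) {
    if (anyNA(cohort[[cn]])) {
      row <- which(is.na(cohort[[cn]]))[1]
      stop(sprintf("missing value in column '%s', row %d", cn, row))
    }
  }
  diabetic <- if ("diabetic" %in% names(cohort)) cohort$diabetic else FALSE
  framingham_points(cohort$age, cohort$total_cholesterol, cohort$hdl,
                    cohort$sbp, cohort$dbp, cohort$smoker,
                    diabetic = diabetic, table = table)
}
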