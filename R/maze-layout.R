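#' Build the canonical four-route maze layout
#'
#' Constructs the maze used throughout the package: a start box at the origin,
#' a central stem leading to a first choice point, left and right stems leading
#' to secondary choice points, and four final alleys converging on three goal
#' boxes. Routes 2 and 3 approach the Centre Goal Box from opposite sides, so
#' two distinct routes share one goal -- the configuration that lets the
#' analyses dissociate route coding from goal coding.
#'
#' The seven enclosures (start box, three choice points, three goal boxes) are
#' regular octagons with a 25 x 25 cm bounding box; the seven connecting alleys
#' are 20 cm long and 10 cm wide. Diagonal alleys run at 45 degrees and join
#' flat octagon faces, so every link has a 45 cm centre-to-centre span. The
#' origin is the start-box centre and y increases toward the goal boxes.
#'
#' @param box_size Flat-to-flat width of the octagonal enclosures (cm).
#' @param alley_length Length of the connecting alleys (cm).
#' @param alley_width Width of the connecting alleys (cm).
#'
#' @return An object of class `maze_layout`: a list with
#'   * `sectors`: named list of 14 polygon matrices (columns `x`, `y`, cm),
#'   * `sector_table`: tibble with one row per sector (`sector`, `kind`,
#'     `distance_rank`, `path_cm`, centre coordinates),
#'   * `routes`: list of four route descriptors, each with the ordered
#'     `sectors` traversed, the destination `goal`, and a piecewise-linear
#'     `centerline` matrix,
#'   * the dimensions used.
#' @examples
#' maze <- build_maze_layout()
#' names(maze$sectors)
#' maze$routes[[2]]$goal
#' @export
build_maze_layout <- function(box_size = 25, alley_length = 20,
                              alley_width = 10) {
  if (!is.numeric(box_size) || length(box_size) != 1 || box_size <= 0 ||
      !is.numeric(alley_length) || length(alley_length) != 1 || alley_length <= 0 ||
      !is.numeric(alley_width) || length(alley_width) != 1 || alley_width <= 0) {
    stop("maze dimensions must be single positive numbers", call. = FALSE)
  }
  a <- box_size / 2                      # octagon apothem
  span <- box_size + alley_length        # centre-to-centre distance per link
  u45 <- c(cos(pi / 4), sin(pi / 4))
  u135 <- c(-u45[1], u45[2])

  centres <- list(
    start_box     = c(0, 0),
    choice_point  = c(0, span),
    left_choice   = c(0, span) + span * u135,
    right_choice  = c(0, span) + span * u45,
    left_goal_box   = c(0, span) + 2 * span * u135,
    centre_goal_box = c(0, span) + span * (u135 + u45),
    right_goal_box  = c(0, span) + 2 * span * u45
  )

  octagon <- function(centre) {
    th <- pi / 8 + (0:7) * pi / 4
    r <- a / cos(pi / 8)
    cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
  }
  alley <- function(from, to) {
    # rectangle of length alley_length, width alley_width between two box faces
    d <- (to - from) / sqrt(sum((to - from)^2))
    n <- c(-d[2], d[1]) * alley_width / 2
    p0 <- from + a * d
    p1 <- to - a * d
    cbind(x = c(p0[1] + n[1], p1[1] + n[1], p1[1] - n[1], p0[1] - n[1]),
          y = c(p0[2] + n[2], p1[2] + n[2], p1[2] - n[2], p0[2] - n[2]))
  }

  sectors <- list(
    start_box          = octagon(centres$start_box),
    central_stem       = alley(centres$start_box, centres$choice_point),
    choice_point       = octagon(centres$choice_point),
    left_stem          = alley(centres$choice_point, centres$left_choice),
    right_stem         = alley(centres$choice_point, centres$right_choice),
    left_choice        = octagon(centres$left_choice),
    right_choice       = octagon(centres$right_choice),
    left_goal_alley    = alley(centres$left_choice, centres$left_goal_box),
    centre_left_alley  = alley(centres$left_choice, centres$centre_goal_box),
    centre_right_alley = alley(centres$right_choice, centres$centre_goal_box),
    right_goal_alley   = alley(centres$right_choice, centres$right_goal_box),
    left_goal_box      = octagon(centres$left_goal_box),
    centre_goal_box    = octagon(centres$centre_goal_box),
    right_goal_box     = octagon(centres$right_goal_box)
  )

  rank_of <- c(start_box = 1, central_stem = 2, choice_point = 3,
               left_stem = 4, right_stem = 4, left_choice = 5, right_choice = 5,
               left_goal_alley = 6, centre_left_alley = 6,
               centre_right_alley = 6, right_goal_alley = 6,
               left_goal_box = 7, centre_goal_box = 7, right_goal_box = 7)
  half <- span / 2
  path_of <- (rank_of - 1) * half        # centreline distance from start centre
  kind_of <- ifelse(grepl("box|choice", names(sectors)) &
                      !grepl("alley|stem", names(sectors)), "enclosure", "alley")

  centroid <- function(p) colMeans(p)
  cent <- t(vapply(sectors, centroid, numeric(2)))
  sector_table <- tibble::tibble(
    sector = names(sectors),
    kind = unname(kind_of),
    distance_rank = unname(rank_of[names(sectors)]),
    path_cm = unname(path_of[names(sectors)]),
    cx = cent[, 1], cy = cent[, 2]
  )

  route_def <- list(
    list(sectors = c("start_box", "central_stem", "choice_point", "left_stem",
                     "left_choice", "left_goal_alley", "left_goal_box"),
         goal = "left",
         via = c("start_box", "choice_point", "left_choice", "left_goal_box")),
    list(sectors = c("start_box", "central_stem", "choice_point", "left_stem",
                     "left_choice", "centre_left_alley", "centre_goal_box"),
         goal = "centre",
         via = c("start_box", "choice_point", "left_choice", "centre_goal_box")),
    list(sectors = c("start_box", "central_stem", "choice_point", "right_stem",
                     "right_choice", "centre_right_alley", "centre_goal_box"),
         goal = "centre",
         via = c("start_box", "choice_point", "right_choice", "centre_goal_box")),
    list(sectors = c("start_box", "central_stem", "choice_point", "right_stem",
                     "right_choice", "right_goal_alley", "right_goal_box"),
         goal = "right",
         via = c("start_box", "choice_point", "right_choice", "right_goal_box"))
  )
  routes <- lapply(route_def, function(r) {
    cl <- do.call(rbind, lapply(r$via, function(nm) centres[[nm]]))
    colnames(cl) <- c("x", "y")
    list(sectors = r$sectors, goal = r$goal, centerline = cl)
  })

  structure(
    list(sectors = sectors, sector_table = sector_table, routes = routes,
         box_size = box_size, alley_length = alley_length,
         alley_width = alley_width),
    class = "maze_layout"
  )
}

#' @export
print.maze_layout <- function(x, ...) {
  cat("<maze_layout>: 14 sectors, 4 routes, 3 goals\n")
  cat(sprintf("  boxes %g x %g cm, alleys %g x %g cm\n",
              x$box_size, x$box_size, x$alley_length, x$alley_width))
  invisible(x)
}

# Even-odd ray-crossing point-in-polygon with a half-open boundary convention:
# a point on an edge shared by two adjacent sectors is counted inside exactly
# one of them, so sector assignment partitions the maze.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y))
    if (any(crosses)) {
      xi <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
      flip <- crosses & (x < xi)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Assign maze sectors to points
#'
#' Labels each (x, y) point with the maze sector containing it, or `NA` for
#' points outside the maze. Shared sector boundaries are resolved by a fixed
#' half-open convention (first containing sector in layout order), so every
#' point belongs to at most one sector.
#'
#' @param data A data frame with numeric columns `x` and `y` (cm).
#' @param layout A [build_maze_layout()] object.
#' @return `data` with a `sector` character column added (or replaced).
#' @export
assign_sectors <- function(data, layout) {
  stopifnot(is.data.frame(data), inherits(layout, "maze_layout"))
  sec <- rep(NA_character_, nrow(data))
  todo <- rep(TRUE, nrow(data))
  for (nm in names(layout$sectors)) {
    if (!any(todo)) break
    hit <- point_in_polygon(data$x[todo], data$y[todo], layout$sectors[[nm]])
    idx <- which(todo)[hit]
    sec[idx] <- nm
    todo[idx] <- FALSE
  }
  data$sector <- sec
  data
}

#' Sector lookup for coordinate vectors
#'
#' Lower-level companion to [assign_sectors()] operating on bare vectors.
#'
#' @param x,y Numeric coordinate vectors (cm).
#' @param layout A [build_maze_layout()] object.
#' @return Character vector of sector names (`NA` outside the maze).
#' @export
sector_at <- function(x, y, layout) {
  assign_sectors(tibble::tibble(x = x, y = y), layout)$sector
}
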