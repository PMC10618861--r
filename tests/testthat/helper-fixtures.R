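# Shared fixtures, built once per test run. Everything is generated in code;
# no binary fixtures on disk.

fix <- new.env()

default_vertebra <- function() {
  if (is.null(fix$vert)) fix$vert <- make_vertebra()
  fix$vert
}

chain2 <- function() {
  if (is.null(fix$chain2)) fix$chain2 <- make_chain(chain_recipe(2))
  fix$chain2
}

chain4 <- function() {
  if (is.null(fix$chain4)) fix$chain4 <- make_chain(chain_recipe(4))
  fix$chain4
}

# two-vertebra chain with parameter overrides
chain2_with <- function(...) {
  make_chain(chain_recipe(2, params = vertebra_params(...)))
}

# set of viable (roll, yaw, pitch) triples as a sorted key vector
pose_key <- function(df) sort(paste(df$roll, df$yaw, df$pitch))

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

random_rigid <- function() {
  ang <- runif(3, -180, 180)
  rigid_transform(rot_x(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3]),
                  runif(3, -10, 10))
}
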