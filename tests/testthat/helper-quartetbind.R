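# shared fixtures built in code

# noiseless titration series on an n-lane log ladder
noiseless_titration <- function(kd1, kcoop, n = 8) {
  simulate_titration(kd1, kcoop, emsa_protein_ladder(n = n),
                     noise = noise_model(sd = 0))
}

# every construct name used on the SEP3-like, AMtrAGL9-like and chimeric
# backgrounds
SEP3_CONSTRUCTS <- c("S94P", "L115P", "L120P-L123P", "L131P-L135P", "L145P",
                     "L164P", "G178P", "L115A", "L145A", "L164A", "L164E",
                     "L164W", "L164I", "E161L-N168L")
AMTR_CONSTRUCTS <- c("I141P", "I141A", "L160P", "L160A")
CHIM_CONSTRUCTS <- c("T157L", "Q164L", "T157L-Q164L")
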