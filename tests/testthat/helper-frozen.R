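# Frozen reference values computed once with independent reference
# implementations of the wavelet filter bank (level-1/2 lowpass
# reconstructions of the signal below) and of topographic prominence, on
# fixed deterministic inputs.

# deterministic 64-point test signal: two tones plus a slow ramp
frozen_dwt_signal <- function() {
  t <- 0:63
  sin(2 * pi * t / 16) + 0.25 * cos(2 * pi * t / 5) + 0.01 * t
}

frozen_approx_level1 <- c(
  0.208351885073781, 0.436400713877603, 0.512353574112303, 0.810160167959789,
  1.23911131723704, 0.92163051118244, 0.936104989914401, 0.369190284831967,
  -0.172113358056628, -0.234472065906184, -0.368177007560904, -0.695441949034006,
  -1.23492594153391, -0.731973730108223, -0.543507522394882, -0.13953350375775,
  0.25629873375976, 0.469190284831967, 0.707692898098012, 1.02669194903401,
  1.61444183207102, 1.04669194903401, 0.747692898098014, 0.529190284831967,
  0.33629873375976, -0.0395335037577496, -0.423507522394881, -0.591973730108223,
  -1.07492594153391, -0.515441949034006, -0.168177007560905, -0.0144720659061845,
  0.0678866419433714, 0.629190284831967, 1.2161049899144, 1.22163051118244,
  1.55911131723704, 1.15016016795979, 0.907692898098013, 0.745722065906185,
  0.711629248593739, 0.0855279340938174, -0.611919614211268, -0.431973730108223,
  -0.566513849717523, -0.320503386885572, -0.223507522394881, 0.088996153019598,
  0.22788664194337, 0.845722065906183, 1.59143550474838, 1.34669194903401,
  1.37069922542065, 1.31016016795979, 1.4161049899144, 0.940660628054619,
  0.656298733759762, 0.1889961530196, -0.451919614211269, -0.215441949034006,
  -0.191183334883545, -0.195441949034006, -0.229642844133114, -0.115557387136714)

frozen_approx_level2 <- c(
  0.512143346050511, 0.592323839327875, 0.724976890193471, 0.654237042509517,
  0.55085227814324, 0.781440079055802, 1.21165907929011, 0.509380716958605,
  0.0906687848590919, -0.329811505602571, -1.0347424054773, -0.600102509337619,
  -0.306976428492586, -0.587365882483372, -1.01299928859742, -0.284141351382601,
  0.156768538091431, 0.594979275199739, 1.31978848386597, 0.900902958666233,
  0.62497927519974, 0.920902958666233, 1.35978848386597, 0.65497927519974,
  0.236768538091431, -0.184141351382601, -0.892999288597418, -0.447365882483372,
  -0.146976428492586, -0.420102509337619, -0.834742405477299, -0.109811505602572,
  0.328460077109985, 0.773798132456818, 1.50932874128296, 1.07702266355759,
  0.792205043694002, 1.08527027893479, 1.51978848386597, 0.810611954931186,
  0.389542769597169, -0.0402610562739559, -0.762539546014405, -0.30618473974045,
  0.00133203248885957, -0.274432355117649, -0.69299928859742, 0.042925121251675,
  0.488460077109984, 0.94106150560257, 1.68758562440308, 1.25135250933762,
  0.963896582712556, 1.26408913619187, 1.70932874128296, 0.986731659822542,
  0.545376239961546, 0.146890860254367, -0.511401160975328, -0.173336656268774,
  -0.00829362608069936, -0.147521223754954, -0.265862660841892, -0.163478112415766)

# 40-point random-walk trace with its reference peak positions (1-based)
# and prominences
frozen_prom_trace <- c(
  0.304717079754431, -0.0808776328937597, 1.25192377545987, 2.6386908553274,
  0.948589499784396, -0.306649894301018, -0.351030552985899, -1.0396962355042,
  -1.58812390321351, -3.07347306793898, -2.85745103494686, -2.70107727094363,
  -3.14609746682158, -2.36328027177921, -2.0356517611815, -2.81488293919516,
  -2.15494238892154, -2.643562690104, -1.16754690170596, -0.558387796530015,
  -0.0952017186971815, -0.210460526805985, 1.43310135366808, 1.50859370633441,
  1.09396680344532, 0.537704975899717, 0.670528375489801, 0.485106980111269,
  0.256237092333243, 0.0253500779709949, 1.55802900332335, 0.662423644271024,
  -0.165378034030281, -1.08633966170335, -0.357379080057416, 1.09230677422126,
  1.4714991730387, 1.24262100027471, 1.08026328747895, 2.37093417786379)

frozen_prom_peaks <- c(4L, 12L, 15L, 17L, 21L, 24L, 27L, 31L, 37L)

frozen_prominences <- c(
  2.71956848822116, 0.372395796995353, 0.779231178013658, 0.488620301182457,
  0.115258808108803, 1.48324362836342, 0.132823399590083, 2.6443686650267,
  0.391235885559752)
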