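# Baroreflex cardiovascular control model: heart rate x1 (bpm) and arterial
# pressure x2 (mmHg) under delayed sympathetic / instantaneous vagal feedback.
# Time is dimensionless (real time / tau), so the sympathetic delay is 1.
# The Hill terms g1 (delayed pressure) and g2 (current pressure) are inlined.
# Initial conditions x1(0) = h0 and x2(0) = p0 are an assumption: the source
# model fixes the parameter set but not the initial state.

[states]
x1 = 100
x2 = 100

[parameters]
h0 = 100       # uncontrolled heart rate, bpm
p0 = 100       # mean arterial blood pressure, mmHg
alpha = 15     # sympathetic effect on peripheral resistance
beta = 10      # sympathetic control of heart rate
nu = 9.63      # strength of vagal tone
delta = 0.8    # relaxation rate, 1/s
gamma = 0.2    # damping of vagal activity on sympathetic tone
mu = 0.18      # pressure coupling, nominal 3/(2 + alpha)
A1 = 0         # respiration amplitude on the delayed (sympathetic) pathway
A2 = 0.003     # respiration amplitude on the instantaneous pathway
f_r = 0.17     # breathing rate, Hz
tau = 3        # sympathetic time delay, s
phi = 3.14     # phase lag, s
n = 8          # Hill exponent
eps_h = 1      # relative coefficient for heart rate
eps_p = 3      # relative coefficient for blood pressure

[delays]
d1 = 1

[equations]
dx1/dt = (h0/eps_h)*(beta*(1/(1 + (x2@d1/p0 + A1*sin(2*pi*f_r*tau*(t - 1) - phi))^n))/(1 + gamma*(1 - 1/(1 + (x2/p0 + A2*sin(2*pi*f_r*tau*t - phi))^n))) - nu*(1 - 1/(1 + (x2/p0 + A2*sin(2*pi*f_r*tau*t - phi))^n))) + (delta/eps_h)*(h0 - x1)
dx2/dt = mu*p0*x1/(eps_p*h0) - x2/(eps_p*(1 + alpha*(1/(1 + (x2@d1/p0 + A1*sin(2*pi*f_r*tau*(t - 1) - phi))^n))))

[options]
t0 = 0
sampling = 0:200:0.02
epsilon = 0.001
iteration_limit = 20
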