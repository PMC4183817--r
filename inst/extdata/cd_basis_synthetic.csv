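# Synthetic far-UV CD basis spectra (mean residue ellipticity,
# deg cm^2 dmol^-1 residue^-1) for the spectrum generator.  Smooth
# Gaussian-band constructions, not digitised reference data; helix and
# coil are anchored at 222 nm to the single-wavelength helicity
# estimator endpoints (N = Inf, T = 0 C).  Built by data-raw/make_cd_basis.R.
wavelength_nm,helix,sheet,coil
185,28662.5,4060,-6455.9
186,35755.3,5744.6,-8615.8
187,42840.6,7864,-11215.5
188,49414.2,10415.2,-14245.5
189,54944.8,13345.1,-17659.6
190,58942.1,16542.9,-21369.9
191,61026.4,19839.2,-25245.8
192,60982.9,23017.2,-29118.8
193,58791.3,25833,-32793
194,54620.3,28045.3,-36060
195,48790,29448,-38718.3
196,41709.8,29899.9,-40593.5
197,33806.6,29345.5,-41557
198,25460.9,27822.6,-41540.8
199,16966.8,25453.4,-40544.8
200,8524,22423.4,-38637.3
201,263.1,18951.2,-35946.9
202,-7706.1,15255.7,-32648.1
203,-15243.4,11527.9,-28942.4
204,-22142.7,7912.3,-25038.3
205,-28131,4498.8,-21131.9
206,-32906.9,1326.3,-17391.7
207,-36211,-1605.1,-13948.2
208,-37906.8,-4317.5,-10889.6
209,-38044.9,-6838,-8262.1
210,-36886.6,-9184,-6075.3
211,-34876.5,-11354.5,-4309.2
212,-32568,-13326.1,-2923.8
213,-30521.3,-15056,-1867
214,-29200.3,-16489.2,-1082.1
215,-28891.3,-17567.8,-514.2
216,-29660.6,-18242,-113.3
217,-31356.6,-18479.5,163.2
218,-33649.2,-18272.3,350
219,-36098.2,-17639.9,473.7
220,-38233.8,-16628.7,554.4
221,-39636.1,-15307.7,606.6
222,-40000,-13761.6,640
223,-39176.2,-12082,661.4
224,-37182.4,-10359.3,675.2
225,-34186.5,-8674.4,683.9
226,-30465,-7093.6,689.4
227,-26350,-5665.2,692.4
228,-22172.7,-4418.6,693.7
229,-18217.8,-3365.7,693.5
230,-14693.3,-2503.7,692
231,-11719.5,-1818.9,689.3
232,-9334.4,-1290.5,685.5
233,-7511.2,-894.2,680.5
234,-6180.1,-605.1,674.5
235,-5250.5,-399.9,667.5
236,-4628.9,-258.1,659.5
237,-4230.4,-162.7,650.5
238,-3985.4,-100.1,640.6
239,-3840.8,-60.2,629.8
240,-3758.8,-35.3,618.2
241,-3714.2,-20.3,605.9
242,-3690.9,-11.3,592.8
243,-3679.2,-6.2,579.1
244,-3673.5,-3.3,564.8
245,-3670.8,-1.7,549.9
246,-3669.7,-0.9,534.6
247,-3669.2,-0.4,518.8
248,-3668.9,-0.2,502.7
249,-3668.9,-0.1,486.3
250,-3668.8,0,469.7
251,-3668.8,0,452.9
252,-3668.8,0,435.9
253,-3668.8,0,419
254,-3668.8,0,402
255,-3668.8,0,385.1
256,-3668.8,0,368.3
257,-3668.8,0,351.6
258,-3668.8,0,335.1
259,-3668.8,0,318.9
260,-3668.8,0,303
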