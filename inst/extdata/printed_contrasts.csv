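scenario_a,scenario_b,metric,item,kind,printed,flag,note
nbp1g,sm0g,compression,C2C3,percent,-75.9,,
nbp1g,sm0g,compression,C3C4,percent,-75.4,,
nbp1g,sm0g,compression,C4C5,percent,-75.4,,
nbp1g,sm0g,compression,C5C6,percent,-76.1,,
nbp1g,sm0g,compression,C6C7,percent,-77.0,,
nbp1g,sm0g,compression,C7T1,percent,-77.9,,
nbp1g,sm0g,shear,C2C3,delta,8.97,,
nbp1g,sm0g,shear,C3C4,delta,11.01,,
nbp1g,sm0g,shear,C4C5,delta,9.76,,
nbp1g,sm0g,shear,C5C6,delta,11.55,,
nbp1g,sm0g,shear,C6C7,delta,10.76,,
nbp1g,sm0g,shear,C7T1,delta,8.19,,
nbp1g,nbp0g,compression,C2C3,percent,-76.6,,
nbp1g,nbp0g,compression,C3C4,percent,-74.7,,
nbp1g,nbp0g,compression,C4C5,percent,-74.7,,
nbp1g,nbp0g,compression,C5C6,percent,-74.8,,
nbp1g,nbp0g,compression,C6C7,percent,-75.7,,
nbp1g,nbp0g,compression,C7T1,percent,-77.1,,
nbp1g,nbp0g,shear,C2C3,delta,7.97,,
nbp1g,nbp0g,shear,C3C4,delta,11.42,,
nbp1g,nbp0g,shear,C4C5,delta,10.24,,
nbp1g,nbp0g,shear,C5C6,delta,12.31,,
nbp1g,nbp0g,shear,C6C7,delta,12.57,,
nbp1g,nbp0g,shear,C7T1,delta,11.6,,
sm0g,nbp0g,compression,C2C3,percent,-2.8,,
sm0g,nbp0g,compression,C3C4,ratio,103.2,,
sm0g,nbp0g,compression,C4C5,ratio,102.7,,
sm0g,nbp0g,compression,C5C6,ratio,105.5,,
sm0g,nbp0g,compression,C6C7,ratio,105.5,,
sm0g,nbp0g,compression,C7T1,ratio,103.4,,
sm0g,nbp0g,shear,C3C4,delta,0.41,,
sm0g,nbp0g,shear,C4C5,delta,0.48,,
sm0g,nbp0g,shear,C5C6,delta,0.76,,
sm0g,nbp0g,shear,C6C7,percent,2011.1,,report phrases this as a ratio of the two shears but the number is the percent change
sm0g,nbp0g,shear,C7T1,percent,1175.9,,report phrases this as a ratio of the two shears but the number is the percent change
nbp1g,sm0g,height,C2C3,percent,1.0,,
nbp1g,sm0g,height,C3C4,percent,1.4,,
nbp1g,sm0g,height,C4C5,percent,1.9,,
nbp1g,sm0g,height,C5C6,percent,3.8,,
nbp1g,sm0g,height,C6C7,percent,1.7,,
nbp1g,sm0g,height,C7T1,percent,1.4,,
nbp1g,sm0g,area,C2C3,percent,2.6,,
nbp1g,sm0g,area,C3C4,percent,4.8,,
nbp1g,sm0g,area,C4C5,percent,4.5,,
nbp1g,sm0g,area,C5C6,percent,2.3,,
nbp1g,sm0g,area,C6C7,percent,5.6,,
nbp1g,sm0g,area,C7T1,percent,5.4,,
nbp1g,sm0g,volume,C2C3,percent,3.6,,
nbp1g,sm0g,volume,C3C4,percent,6.3,,
nbp1g,sm0g,volume,C4C5,percent,6.5,,
nbp1g,sm0g,volume,C5C6,percent,6.1,c5c6_volume,consistent with the corrected volume 2818.4 (=5.2x542) not the tabulated 2814.4; recomputed value is 6.0
nbp1g,sm0g,volume,C6C7,percent,7.3,,
nbp1g,sm0g,volume,C7T1,percent,6.8,,
nbp1g,nbp0g,height,C2C3,percent,1.6,,
nbp1g,nbp0g,height,C3C4,percent,2.6,,
nbp1g,nbp0g,height,C4C5,percent,2.2,,
nbp1g,nbp0g,height,C5C6,percent,4.8,,
nbp1g,nbp0g,height,C6C7,percent,1.9,,
nbp1g,nbp0g,height,C7T1,percent,2.7,,
nbp1g,nbp0g,area,C2C3,percent,3.2,,
nbp1g,nbp0g,area,C3C4,percent,5.2,,
nbp1g,nbp0g,area,C4C5,percent,5.1,,
nbp1g,nbp0g,area,C5C6,percent,3.2,,
nbp1g,nbp0g,area,C6C7,percent,6.9,,
nbp1g,nbp0g,area,C7T1,percent,6.5,,
nbp1g,nbp0g,volume,C2C3,percent,4.8,,
nbp1g,nbp0g,volume,C3C4,percent,7.9,,
nbp1g,nbp0g,volume,C4C5,percent,7.4,,
nbp1g,nbp0g,volume,C5C6,percent,8.2,,
nbp1g,nbp0g,volume,C6C7,percent,8.9,,
nbp1g,nbp0g,volume,C7T1,percent,9.4,,
nbp0g,sm0g,height,C2C3,percent,-0.4,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,height,C3C4,percent,-4.1,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,height,C4C5,percent,-5.1,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,height,C5C6,percent,-1.4,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,height,C6C7,percent,-8.3,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,height,C7T1,percent,-6.5,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C2C3,percent,-1.1,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C3C4,percent,-1.8,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C4C5,percent,-3.3,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C5C6,percent,-4.4,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C6C7,percent,-1.4,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,area,C7T1,percent,-1.7,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C2C3,percent,-1.5,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C3C4,percent,-6.0,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C4C5,percent,-1.9,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C5C6,percent,-5.8,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C6C7,percent,-9.9,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp0g,sm0g,volume,C7T1,percent,-8.3,sec323,not derivable from the tabulated per-scenario states under any convention tried
nbp1g,sm0g,phi_np,C2C3,percent,6.2,rounding_tie,exact value 6.25; half-away-from-zero rounding gives 6.3
nbp1g,sm0g,phi_np,C3C4,percent,5.6,,
nbp1g,sm0g,phi_np,C4C5,percent,7.2,,
nbp1g,sm0g,phi_np,C5C6,percent,2.4,,
nbp1g,sm0g,phi_np,C6C7,percent,1.2,,
nbp1g,sm0g,phi_np,C7T1,percent,3.1,,
nbp1g,sm0g,phi_af,C2C3,percent,2.7,,
nbp1g,sm0g,phi_af,C3C4,percent,3.7,,
nbp1g,sm0g,phi_af,C4C5,percent,3.8,,
nbp1g,sm0g,phi_af,C5C6,percent,1.0,,
nbp1g,sm0g,phi_af,C6C7,percent,1.3,,
nbp1g,sm0g,phi_af,C7T1,percent,0.3,,
nbp1g,nbp0g,phi_np,C2C3,percent,8.8,,
nbp1g,nbp0g,phi_np,C3C4,percent,6.1,,
nbp1g,nbp0g,phi_np,C4C5,percent,7.9,,
nbp1g,nbp0g,phi_np,C5C6,percent,3.6,,
nbp1g,nbp0g,phi_np,C6C7,percent,1.8,,
nbp1g,nbp0g,phi_np,C7T1,percent,3.8,,
nbp1g,nbp0g,phi_af,C2C3,percent,4.4,,
nbp1g,nbp0g,phi_af,C3C4,percent,3.9,,
nbp1g,nbp0g,phi_af,C4C5,percent,3.9,,
nbp1g,nbp0g,phi_af,C5C6,percent,1.3,,
nbp1g,nbp0g,phi_af,C6C7,percent,2.6,,
nbp1g,nbp0g,phi_af,C7T1,percent,0.9,,
sm0g,nbp0g,phi_np,C2C3,percent,2.4,,
sm0g,nbp0g,phi_np,C3C4,percent,0.5,,
sm0g,nbp0g,phi_np,C4C5,percent,0.7,,
sm0g,nbp0g,phi_np,C5C6,percent,1.2,,
sm0g,nbp0g,phi_np,C6C7,percent,0.6,,
sm0g,nbp0g,phi_np,C7T1,percent,0.7,,
sm0g,nbp0g,phi_af,C2C3,percent,1.7,,
sm0g,nbp0g,phi_af,C3C4,percent,0.3,,
sm0g,nbp0g,phi_af,C4C5,percent,0.1,,
sm0g,nbp0g,phi_af,C5C6,percent,0.3,,
sm0g,nbp0g,phi_af,C6C7,percent,1.3,,
sm0g,nbp0g,phi_af,C7T1,percent,0.7,,
nbp1g,sm0g,ligament_force,ALL,percent,147.1,,
nbp1g,sm0g,ligament_force,PLL,percent,190.6,,
nbp1g,sm0g,ligament_force,LF,percent,113.5,,
nbp1g,nbp0g,ligament_force,ALL,percent,141.2,,
nbp1g,nbp0g,ligament_force,PLL,percent,205.7,,
nbp1g,nbp0g,ligament_force,LF,percent,105.4,,
nbp0g,sm0g,ligament_force,ALL,percent,2.4,,
nbp0g,sm0g,ligament_force,PLL,percent,-4.9,,
nbp0g,sm0g,ligament_force,LF,percent,3.9,rounding_slip,exact value 3.9548 rounds to 4.0 under any half rule
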