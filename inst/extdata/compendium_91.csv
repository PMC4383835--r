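code,label,category,subcategory,met
H01,"cooking, light meal preparation",household,cooking,2.0
H02,"cooking, standing kitchen work",household,cooking,3.3
H03,washing dishes,household,dishwashing,2.5
H04,vacuuming,household,cleaning,3.3
H05,mopping or scrubbing floors,household,cleaning,3.5
H06,"tidying, light cleaning",household,cleaning,2.5
H07,laundry (washing and hanging),household,laundry,2.0
H08,ironing,household,laundry,1.8
H09,food shopping with cart,household,shopping,2.3
H10,errands and shopping on foot,household,shopping,2.5
H11,"childcare, bathing and feeding",household,childcare,3.0
H12,"playing with children, light",household,childcare,2.5
H13,carrying or actively playing with child,household,childcare,3.5
H14,elder or family care,household,family_care,2.8
H15,pet care and dog walking,household,pet_care,3.0
H16,"home repair, light",household,home_repair,3.0
H17,making beds and airing futon,household,cleaning,2.0
H18,taking out trash,household,household_misc,2.5
H19,sewing or knitting,household,household_misc,1.3
H20,household paperwork,household,household_misc,1.5
T01,walking to or from work or station,transportation,commute_walk,3.5
T02,"walking for errands, transport",transportation,transport_walk_other,3.0
T03,"riding train or bus, seated",transportation,commute_transit,1.3
T04,standing in train or bus,transportation,commute_transit,2.0
T05,driving a car,transportation,commute_car_sitting,2.0
T06,riding as car passenger,transportation,commute_car_sitting,1.3
T07,bicycling for transportation,transportation,cycling_transport,4.0
T08,motorcycle or scooter,transportation,transport_other,2.5
T09,"waiting for transport, standing",transportation,transport_other,1.8
T10,taxi ride,transportation,commute_car_sitting,1.3
W01,"desk work, sitting",work,work_sitting,1.5
W02,"meetings, sitting",work,work_sitting,1.5
W03,"computer work, sitting",work,work_sitting,1.5
W04,"standing work, sales or teaching",work,work_standing,3.0
W05,"standing work, light assembly",work,work_standing,3.0
W06,walking at work carrying light loads,work,work_walking,3.5
W07,heavy manual labor (construction),work,work_vigorous,5.5
W08,"farming, general",work,work_vigorous,5.5
W09,loading or carrying heavy loads,work,work_vigorous,6.5
W10,"delivery work, walking and carrying",work,work_walking,4.0
W11,restaurant kitchen work,work,work_standing,3.0
W12,nursing or care work,work,work_standing,3.0
W13,professional driving,work,work_sitting,2.0
W14,reception or counter service standing,work,work_standing,3.0
W15,business walking between sites,work,work_walking,3.5
L01,watching television,leisure_sports,screen_leisure,1.3
L02,reading,leisure_sports,quiet_leisure,1.3
L03,computer or internet leisure,leisure_sports,screen_leisure,1.5
L04,video games,leisure_sports,screen_leisure,1.5
L05,listening to music,leisure_sports,quiet_leisure,1.3
L06,"conversation, socializing seated",leisure_sports,social_leisure,1.5
L07,telephone,leisure_sports,social_leisure,1.5
L08,hobby crafts seated,leisure_sports,quiet_leisure,1.8
L09,playing musical instrument,leisure_sports,quiet_leisure,2.0
L10,board or card games,leisure_sports,quiet_leisure,1.5
L11,"relaxing, sitting quietly",leisure_sports,quiet_leisure,1.0
L12,walking for pleasure,leisure_sports,sport_exercise,3.5
L13,brisk walking for exercise,leisure_sports,sport_exercise,4.3
L14,jogging,leisure_sports,sport_exercise,7.0
L15,running,leisure_sports,sport_exercise,8.3
L16,cycling for exercise,leisure_sports,sport_exercise,6.8
L17,swimming laps,leisure_sports,sport_exercise,6.0
L18,tennis,leisure_sports,sport_exercise,7.3
L19,"golf, walking course",leisure_sports,sport_exercise,4.8
L20,baseball or softball,leisure_sports,sport_exercise,5.0
L21,soccer or futsal,leisure_sports,sport_exercise,7.0
L22,basketball,leisure_sports,sport_exercise,6.5
L23,volleyball,leisure_sports,sport_exercise,4.0
L24,badminton,leisure_sports,sport_exercise,5.5
L25,table tennis,leisure_sports,sport_exercise,4.0
L26,hiking or mountain climbing,leisure_sports,sport_exercise,6.0
L27,strength training,leisure_sports,sport_exercise,5.0
L28,gym fitness class or aerobics,leisure_sports,sport_exercise,6.5
L29,yoga or stretching,leisure_sports,sport_light,2.5
L30,calisthenics (radio exercises),leisure_sports,sport_exercise,3.5
L31,dance,leisure_sports,sport_exercise,4.5
L32,martial arts,leisure_sports,sport_exercise,7.8
L33,skiing or snowboarding,leisure_sports,sport_exercise,5.3
L34,fishing,leisure_sports,outdoor_leisure,2.5
L35,gardening,leisure_sports,car_wash_gardening,3.8
L36,washing the car,leisure_sports,car_wash_gardening,3.5
L37,"yard work, general",leisure_sports,car_wash_gardening,4.0
L38,playing catch or light outdoor play,leisure_sports,outdoor_leisure,3.0
L39,karaoke or singing,leisure_sports,social_leisure,1.8
L40,eating out with friends,leisure_sports,social_leisure,1.5
L41,attending events or movies,leisure_sports,social_leisure,1.5
L42,sightseeing on foot,leisure_sports,outdoor_leisure,2.8
L43,studying or attending classes,leisure_sports,quiet_leisure,1.8
L44,religious or community activities,leisure_sports,social_leisure,2.0
L45,"volunteering, light",leisure_sports,social_leisure,2.5
L46,bowling,leisure_sports,sport_exercise,3.8
SLEEP,sleeping,uncategorized,sleep,0.9
PCARE,"personal care, washing and dressing",uncategorized,personal_care,2.0
EAT,eating a meal,uncategorized,eating,1.5
BATH,bathing,uncategorized,bathing,1.3
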